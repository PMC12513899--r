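#' Percentage decrease in effect-size magnitude
#'
#' `100 * (1 - |replication| / |original|)`: 75 means the replication
#' estimate is a quarter of the original's magnitude; negative values mean
#' the replication came out larger.
#'
#' @param es_original,es_replication Effect sizes of the same kind
#'   ([effect_size()] objects or plain numbers).
#' @return Percentage decrease (a plain number).
#' @export
pct_decrease <- function(es_original, es_replication) {
  val <- function(x) if (inherits(x, "effect_size")) x$value else x
  o <- abs(val(es_original)); r <- abs(val(es_replication))
  if (inherits(es_original, "effect_size") &&
      inherits(es_replication, "effect_size") &&
      es_original$kind != es_replication$kind)
    stop("effect kinds differ; percentage decrease undefined", call. = FALSE)
  if (o == 0)
    stop("original effect is zero; percentage decrease undefined",
         call. = FALSE)
  100 * (1 - r / o)
}

#' Column registry of the project-table CSV schema
#'
#' One row per column of the on-disk project table: name, storage type and
#' whether the column is required for a file to parse. Optional cells are
#' serialised as empty strings and read back as missing, never as zero.
#'
#' @return A data frame with columns `name`, `type`, `required`.
#' @export
project_columns <- function() {
  reg <- function(name, type, required) data.frame(
    name = name, type = type, required = required, stringsAsFactors = FALSE)
  rbind(
    reg("study_id",           "character", TRUE),
    reg("discipline",         "character", FALSE),
    reg("design",             "character", TRUE),
    reg("n_original",         "integer",   TRUE),
    reg("n_replication",      "integer",   TRUE),
    reg("true_effect",        "numeric",   FALSE),
    reg("es_kind",            "character", TRUE),
    reg("es_original",        "numeric",   TRUE),
    reg("se_original",        "numeric",   FALSE),
    reg("es_replication",     "numeric",   TRUE),
    reg("se_replication",     "numeric",   FALSE),
    reg("p_original",         "numeric",   FALSE),
    reg("p_replication",      "numeric",   FALSE),
    reg("rep_significant",    "logical",   TRUE),
    reg("same_direction",     "logical",   TRUE),
    reg("z_comparison",       "numeric",   FALSE),
    reg("p_comparison",       "numeric",   FALSE),
    reg("compatible",         "logical",   TRUE),
    reg("outcome",            "character", TRUE),
    reg("pct_decrease",       "numeric",   FALSE),
    reg("plan_method",        "character", FALSE),
    reg("selection_attempts", "integer",   FALSE))
}

#' Write a project table to CSV
#'
#' Comma-separated, UTF-8, `.` decimal separator, header row, one study
#' pair per row; missing optional fields become empty cells.
#'
#' @param table A `"project_table"` (or compatible data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_project <- function(table, path) {
  stopifnot(is.data.frame(table))
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a project table from CSV
#'
#' Validates the header against [project_columns()] (a missing required
#' column is an error naming that column), then converts each column to
#' its registered type; an unparseable cell is an error naming the row and
#' column. Empty cells in optional columns come back as `NA`, never 0.
#'
#' @param path CSV file path.
#' @return A `"project_table"` data frame.
#' @export
read_project <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE, na.strings = NULL,
                         check.names = FALSE)
  schema <- project_columns()
  missing_req <- setdiff(schema$name[schema$required], names(raw))
  if (length(missing_req))
    stop("project table is missing required column(s): ",
         paste0("'", missing_req, "'", collapse = ", "), call. = FALSE)
  out <- raw
  for (j in intersect(schema$name, names(raw))) {
    type <- schema$type[schema$name == j]
    x <- raw[[j]]
    blank <- is.na(x) | x == ""
    conv <- switch(type,
      character = x,
      integer = suppressWarnings(as.integer(x)),
      numeric = suppressWarnings(as.numeric(x)),
      logical = {
        v <- rep(NA, length(x))
        v[x %in% c("TRUE", "true", "T", "1")] <- TRUE
        v[x %in% c("FALSE", "false", "F", "0")] <- FALSE
        v
      })
    bad <- which(!blank & is.na(conv) & type != "character")
    if (length(bad))
      stop(sprintf("cannot parse cell at row %d, column '%s': \"%s\"",
                   bad[1], j, x[bad[1]]), call. = FALSE)
    conv[blank] <- NA
    out[[j]] <- conv
  }
  class(out) <- c("project_table", "data.frame")
  out
}

#' Aggregate a project table into headline statistics
#'
#' Computes the project-level summary a replication report leads with:
#' the share of replications that were significant, the share of pairs
#' with compatible effects, the share whose effect regressed to a smaller
#' magnitude, the median percentage decrease in magnitude (overall --
#' pooled across effect-size kinds, whose scales differ -- and per kind),
#' the verdict counts, and mean sample sizes. Each statistic is computed
#' over the records that carry the needed fields, and its denominator is
#' reported alongside.
#'
#' @param table A `"project_table"`.
#' @return An object of class `"aggregate_report"` (a list).
#' @export
aggregate_project <- function(table) {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0) stop("project table is empty", call. = FALSE)
  pc <- function(x) {
    n <- sum(!is.na(x))
    list(value = if (n) 100 * mean(x, na.rm = TRUE) else NA_real_, n = n)
  }
  dec <- table$pct_decrease
  counts <- table(factor(table$outcome, levels = replication_verdicts))
  by_kind <- tapply(dec, table$es_kind,
                    function(x) stats::median(x, na.rm = TRUE))
  structure(list(
    n_studies = nrow(table),
    pct_significant = pc(table$rep_significant),
    pct_compatible = pc(table$compatible),
    pct_regressed = pc(dec > 0),
    median_pct_decrease = list(
      value = stats::median(dec, na.rm = TRUE), n = sum(!is.na(dec))),
    median_pct_decrease_by_kind = as.list(by_kind),
    outcome_counts = as.list(counts),
    mean_n_original = mean(table$n_original, na.rm = TRUE),
    mean_n_replication = mean(table$n_replication, na.rm = TRUE)),
    class = "aggregate_report")
}

#' @export
print.aggregate_report <- function(x, ...) {
  cat(sprintf("<aggregate_report> %d study pairs\n", x$n_studies))
  cat(sprintf("  replication significant: %5.1f%%  (n = %d)\n",
              x$pct_significant$value, x$pct_significant$n))
  cat(sprintf("  effects compatible:      %5.1f%%  (n = %d)\n",
              x$pct_compatible$value, x$pct_compatible$n))
  cat(sprintf("  effect regressed:        %5.1f%%  (n = %d)\n",
              x$pct_regressed$value, x$pct_regressed$n))
  cat(sprintf("  median %% decrease:       %5.1f   (n = %d)\n",
              x$median_pct_decrease$value, x$median_pct_decrease$n))
  for (k in names(x$median_pct_decrease_by_kind))
    cat(sprintf("    %-16s %6.1f\n", k, x$median_pct_decrease_by_kind[[k]]))
  cat("  outcomes:",
      paste(sprintf("%s = %d", names(x$outcome_counts),
                    unlist(x$outcome_counts)), collapse = ", "), "\n")
  cat(sprintf("  mean n: original %.1f, replication %.1f\n",
              x$mean_n_original, x$mean_n_replication))
  invisible(x)
}

#' Assess one original/replication pair from summary statistics
#'
#' The per-study pipeline in one call: re-run the replication's test,
#' recompute the design-appropriate effect sizes for both studies with
#' their standard errors, run the compatibility test (Z-test for the
#' d family, Fisher-z for partial eta squared), and classify the outcome.
#'
#' @param original,replication [study_summary()] objects with the same
#'   design family.
#' @return A list with `test_original`, `test_replication`, `es_original`,
#'   `es_replication`, `comparison`, `same_direction`, `outcome` and
#'   `pct_decrease`.
#' @export
assess_study <- function(original, replication) {
  stopifnot(inherits(original, "study_summary"),
            inherits(replication, "study_summary"))
  if (is_t_design(original$design) != is_t_design(replication$design))
    stop("original and replication designs belong to different test ",
         "families", call. = FALSE)
  to <- run_test_from_summary(original)
  tr <- run_test_from_summary(replication)
  if (is_t_design(original$design)) {
    es_o <- se_of_effect(
      d_from_t(to$statistic, original$design,
               n1 = original$n1, n2 = original$n2), original)
    es_r <- se_of_effect(
      d_from_t(tr$statistic, replication$design,
               n1 = replication$n1, n2 = replication$n2), replication)
    if (es_o$kind != es_r$kind)
      stop("original and replication effect kinds differ", call. = FALSE)
    flip <- if (es_o$value < 0) -1 else 1
    es_o$value <- flip * es_o$value
    es_r$value <- flip * es_r$value
    comparison <- z_compare(es_o, es_r)
    same_direction <- es_r$value > 0
  } else {
    es_o <- se_of_effect(
      peta_from_F(to$statistic, to$df1, to$df2), original)
    es_r <- se_of_effect(
      peta_from_F(tr$statistic, tr$df1, tr$df2), replication)
    comparison <- fisherz_compare_peta(es_o, total_n(original),
                                       es_r, total_n(replication))
    same_direction <- if (to$direction == "undefined" ||
                          tr$direction == "undefined") TRUE
                      else to$direction == tr$direction
  }
  list(test_original = to, test_replication = tr,
       es_original = es_o, es_replication = es_r,
       comparison = comparison, same_direction = same_direction,
       outcome = classify_outcome(tr, same_direction, comparison),
       pct_decrease = pct_decrease(es_o, es_r))
}
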
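#' Read a long-format expression time-course table
#'
#' Reads a tab- or comma-delimited table with columns `gene`, `strain`,
#' `replicate`, `time_min`, `value` (one row per measurement) and validates it:
#' duplicated (gene, strain, replicate, time) combinations are an error, values
#' must be nonnegative or `NA` (an `NA` marks a measurement flagged invalid),
#' and every (gene, strain) series is returned on a strictly increasing time
#' grid. Row order in the file does not matter.
#'
#' @param path Path to a `.tsv`/`.txt` (tab) or `.csv` (comma) file with a
#'   header line.
#' @return A tibble with columns `gene`, `strain`, `replicate`, `time_min`,
#'   `value`, ordered by gene, strain, replicate, time.
#' @export
read_timecourse_table <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(
    path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      gene = readr::col_character(),
      strain = readr::col_character(),
      replicate = readr::col_character(),
      time_min = readr::col_double(),
      value = readr::col_double()
    )
  )
  validate_timecourse(as_tibble(raw))
}

#' Validate a long-format time-course table
#'
#' @param panel Tibble with columns `gene`, `strain`, `replicate`, `time_min`,
#'   `value`.
#' @return The validated tibble, sorted by gene, strain, replicate, time.
#' @export
validate_timecourse <- function(panel) {
  stopifnot_cols(panel, c("gene", "strain", "replicate", "time_min", "value"),
                 "time-course table")
  if (!all(panel$strain %in% c("parent", "knockout"))) {
    abort("strain must be one of 'parent' or 'knockout'")
  }
  key <- paste(panel$gene, panel$strain, panel$replicate, panel$time_min,
               sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    first <- panel[dup[1], ]
    abort(sprintf(
      "duplicated measurement for gene '%s', strain '%s', replicate '%s', time %g",
      first$gene, first$strain, first$replicate, first$time_min
    ))
  }
  if (any(!is.na(panel$value) & panel$value < 0)) {
    abort("expression values must be nonnegative (use NA to flag invalid points)")
  }
  if (any(!is.finite(panel$time_min))) abort("times must be finite")
  panel %>%
    arrange(.data$gene, .data$strain, .data$replicate, .data$time_min)
}

#' Write a time-course table
#'
#' Writes the long-format table as tab-delimited text with a header; numeric
#' values are serialized with 12 significant digits so that decimal inputs of
#' up to 12 significant digits round-trip exactly.
#'
#' @param panel Long time-course tibble (see [read_timecourse_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timecourse_table <- function(panel, path) {
  stopifnot_cols(panel, c("gene", "strain", "replicate", "time_min", "value"),
                 "time-course table")
  out <- panel
  out$time_min <- sprintf("%.12g", out$time_min)
  out$value <- ifelse(is.na(out$value), "NA", sprintf("%.12g", out$value))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a binding-curve table
#'
#' @param path Tab- or comma-delimited file with columns `time_min`,
#'   `enrichment` (fold enrichment, 1 = no binding).
#' @return Tibble sorted by time with positive enrichment values.
#' @export
read_binding_table <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  curve <- readr::read_delim(
    path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      time_min = readr::col_double(),
      enrichment = readr::col_double()
    )
  )
  curve <- arrange(as_tibble(curve), .data$time_min)
  if (any(duplicated(curve$time_min))) abort("duplicate binding time points")
  if (any(curve$enrichment <= 0)) abort("fold enrichment must be > 0")
  curve
}

#' Write a binding-curve table
#'
#' @param curve Tibble with columns `time_min`, `enrichment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_binding_table <- function(curve, path) {
  stopifnot_cols(curve, c("time_min", "enrichment"), "binding curve")
  out <- tibble(
    time_min = sprintf("%.12g", curve$time_min),
    enrichment = sprintf("%.12g", curve$enrichment)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalize counts by total counts per sample
#'
#' A sample is one strain x replicate x time point. Each sample's values are
#' rescaled so that all per-sample totals equal the grand mean of the original
#' totals; relative proportions of genes within a sample are unchanged, and the
#' output stays on the original count scale.
#'
#' @param panel Long time-course tibble (all genes measured in every sample).
#' @return Tibble of the same shape with normalized `value`s.
#' @export
normalize_total_counts <- function(panel) {
  stopifnot_cols(panel, c("gene", "strain", "replicate", "time_min", "value"),
                 "panel")
  totals <- panel %>%
    group_by(.data$strain, .data$replicate, .data$time_min) %>%
    summarise(total = sum(.data$value, na.rm = TRUE), .groups = "drop")
  if (any(totals$total <= 0)) {
    bad <- totals[totals$total <= 0, ][1, ]
    abort(sprintf(
      "sample (strain '%s', replicate '%s', time %g) has zero total counts",
      bad$strain, bad$replicate, bad$time_min
    ))
  }
  target <- mean(totals$total)
  panel %>%
    left_join(totals, by = c("strain", "replicate", "time_min")) %>%
    mutate(value = .data$value * target / .data$total) %>%
    select(-"total")
}

#' Mean-center and unit-scale one trace
#'
#' Standardizes a numeric trace to mean 0 and sample standard deviation 1
#' (n - 1 denominator). Constant traces are an error: they carry no shape
#' information and must be excluded from correlation-based clustering.
#'
#' @param x Numeric vector with at least two distinct finite values.
#' @return Standardized numeric vector.
#' @export
#' @examples
#' standardize_gene(c(1, 2, 3))
standardize_gene <- function(x) {
  x <- as.numeric(x)
  ok <- is.finite(x)
  if (sum(ok) < 2 || isTRUE(sd(x[ok]) == 0) || length(unique(x[ok])) < 2) {
    abort("constant or degenerate trace cannot be standardized; exclude it from clustering")
  }
  (x - mean(x[ok])) / sd(x[ok])
}

#' Standardized mean expression profiles for clustering
#'
#' Averages replicates, then mean-centers and unit-scales each gene's trace
#' within the requested strain. Genes whose mean trace is constant are dropped
#' with a warning (they cannot enter a correlation-distance clustering).
#'
#' @param panel Long time-course tibble.
#' @param strain Which strain's profiles to extract (`"parent"` default).
#' @return Long tibble with columns `gene`, `time_min`, `value` where each
#'   gene's values have mean 0 and sd 1.
#' @export
standardize_profiles <- function(panel, strain = "parent") {
  traces <- mean_trace(panel) %>% filter(.data$strain == !!strain)
  const <- traces %>%
    group_by(.data$gene) %>%
    summarise(constant = sd(.data$value, na.rm = TRUE) == 0, .groups = "drop")
  if (any(const$constant)) {
    warn(sprintf(
      "dropping %d constant trace(s): %s",
      sum(const$constant),
      paste(const$gene[const$constant], collapse = ", ")
    ))
    traces <- traces %>% filter(!.data$gene %in% const$gene[const$constant])
  }
  traces %>%
    group_by(.data$gene) %>%
    mutate(value = standardize_gene(.data$value)) %>%
    ungroup() %>%
    select("gene", "time_min", "value")
}

#' Efficiency-corrected qPCR relative quantification
#'
#' Ratio-of-ratios fold change of a target transcript relative to a reference
#' transcript between a condition sample and a calibrator sample, using the
#' measured per-primer-pair amplification efficiencies:
#' \deqn{FC = E_t^{\Delta Cq_t} / E_r^{\Delta Cq_r}}
#' with \eqn{\Delta Cq = Cq_{calibrator} - Cq_{condition}} for each gene and
#' efficiencies expressed as per-cycle amplification factors in (1, 2].
#'
#' @param condition,calibrator One-row data frames (or named lists) with fields
#'   `target_Cq`, `reference_Cq`, `target_efficiency`, `reference_efficiency`.
#'   Both measurements must share the same efficiencies.
#' @return Dimensionless fold change (scalar).
#' @export
#' @examples
#' m1 <- list(target_Cq = 20, reference_Cq = 18,
#'            target_efficiency = 2, reference_efficiency = 2)
#' m2 <- list(target_Cq = 21, reference_Cq = 18,
#'            target_efficiency = 2, reference_efficiency = 2)
#' relative_quantification(m1, m2) # one perfect-efficiency doubling
relative_quantification <- function(condition, calibrator) {
  get1 <- function(m, f) {
    v <- m[[f]]
    if (is.null(v) || !is.finite(v)) abort(sprintf("field '%s' must be finite", f))
    as.numeric(v)
  }
  et <- get1(condition, "target_efficiency")
  er <- get1(condition, "reference_efficiency")
  if (et != get1(calibrator, "target_efficiency") ||
      er != get1(calibrator, "reference_efficiency")) {
    abort("condition and calibrator must share amplification efficiencies")
  }
  if (et <= 1 || er <= 1 || et > 2 || er > 2) {
    abort("amplification efficiencies must lie in (1, 2]")
  }
  for (f in c("target_Cq", "reference_Cq")) {
    if (get1(condition, f) <= 0 || get1(calibrator, f) <= 0) {
      abort("Cq values must be positive")
    }
  }
  d_target <- get1(calibrator, "target_Cq") - get1(condition, "target_Cq")
  d_ref <- get1(calibrator, "reference_Cq") - get1(condition, "reference_Cq")
  et^d_target / er^d_ref
}
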
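#' Bundled reference cohort of twelve revision specimens
#'
#' Per-specimen TrABL ratios (percent) in the six anatomical subregions
#' for twelve highly deficient hemipelves (eleven Paprosky type IIIb, one
#' type IIc), with age, sex and defect type. Used by the cohort summary
#' stage and as a worked example.
#'
#' @return Data frame with columns `specimen`, `age`, `sex`, `type`,
#'   `PostInf`, `Inf`, `AntInf`, `AntSup`, `PostSup`, `Med`.
#' @export
trabl_cohort <- function() {
  read_cohort(system.file("extdata", "cohort12.csv", package = "trabl"))
}

#' Read a cohort ratio table
#'
#' @param path CSV with columns `specimen`, `age`, `sex`, `type`, and the
#'   six region ratio columns.
#' @return Validated data frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  need <- c("specimen", region_names())
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (rg in region_names()) {
    if (!is.numeric(df[[rg]]))
      stop("cohort table: non-numeric ratio in column ", rg,
           call. = FALSE)
  }
  df
}

#' Summarize a cohort of per-region TrABL ratios
#'
#' Computes, per specimen, the minimum and maximum region ratio and the
#' number of regions strictly exceeding each threshold; per region, the
#' minimum and maximum across specimens and the number of specimens
#' strictly exceeding each threshold; and, per threshold, how many
#' specimens have at least k regions above it ("exceeding" is read as
#' strict inequality throughout).
#'
#' @param table cohort data frame (see [read_cohort()]), >= 1 row.
#' @param thresholds percent thresholds (default slight/moderate/severe:
#'   15, 25, 50).
#' @return A list of class `trabl_cohort_summary`: `per_specimen`,
#'   `per_region` (data frames), and `specimens_with_k_regions` (matrix,
#'   thresholds x k = 1..6: number of specimens with >= k regions above
#'   the threshold).
#' @export
summarize_cohort <- function(table, thresholds = c(15, 25, 50)) {
  if (nrow(table) < 1L)
    stop("cohort table must have at least one row", call. = FALSE)
  regs <- region_names()
  rat <- as.matrix(table[, regs])
  if (!is.numeric(rat) || anyNA(rat))
    stop("cohort table: ratios must be numeric", call. = FALSE)
  per_specimen <- data.frame(
    specimen = table$specimen,
    min = apply(rat, 1L, min),
    max = apply(rat, 1L, max))
  for (th in thresholds)
    per_specimen[[paste0("n_regions_over_", th)]] <-
      rowSums(rat > th)
  per_region <- data.frame(
    region = regs,
    min = apply(rat, 2L, min),
    max = apply(rat, 2L, max),
    row.names = NULL)
  for (th in thresholds)
    per_region[[paste0("n_specimens_over_", th)]] <-
      colSums(rat > th)
  kmat <- t(vapply(thresholds, function(th) {
    nr <- rowSums(rat > th)
    vapply(1:6, function(k) sum(nr >= k), numeric(1))
  }, numeric(6)))
  dimnames(kmat) <- list(paste0("over_", thresholds), paste0("k", 1:6))
  structure(list(per_specimen = per_specimen, per_region = per_region,
                 specimens_with_k_regions = kmat,
                 thresholds = thresholds),
            class = "trabl_cohort_summary")
}

#' @export
print.trabl_cohort_summary <- function(x, ...) {
  cat("Cohort summary (", nrow(x$per_specimen), "specimens )\n")
  cat("\nPer region (min/max and specimens strictly exceeding):\n")
  print(x$per_region, row.names = FALSE)
  cat("\nSpecimens with >= k regions exceeding a threshold:\n")
  print(x$specimens_with_k_regions)
  invisible(x)
}
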
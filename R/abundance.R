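#' Spectral-count abundance index
#'
#' Normalizes a protein's peptide count by the total counts in the sample
#' and by the protein's molecular weight, giving a dimensionless index
#' comparable across pulldowns:
#' `abundance_index = count / (total_counts * mw_kda)`.
#'
#' @param count peptide count(s), non-negative.
#' @param total_counts total counts in the sample (> 0).
#' @param mw_kda molecular weight(s) in kDa (> 0).
#' @return Numeric abundance index (vectorized over `count`/`mw_kda`).
#' @examples
#' abundance_index(4, 1000, 56)  # 7.14e-5
#' @export
abundance_index <- function(count, total_counts, mw_kda) {
  stop_if_not_scalar_num(total_counts, "total_counts", positive = TRUE)
  if (any(mw_kda <= 0)) stop("'mw_kda' must be > 0", call. = FALSE)
  if (any(count < 0)) stop("counts must be >= 0", call. = FALSE)
  count / (total_counts * mw_kda)
}

#' Bait-vs-mock abundance enrichment screen
#'
#' Computes abundance indices in a bait pulldown and a mock (untransfected
#' control) pulldown and ranks proteins by the bait/mock index ratio, the
#' screen used to nominate candidate bait-associated proteins. A
#' pseudocount (default 1) is added to both raw counts so proteins absent
#' from the mock get a finite ratio; sample totals are the raw totals.
#' Proteins absent from both tables are excluded.
#'
#' @param bait,mock data frames with columns `protein_id`, `mw_kda`,
#'   `count` (e.g. from [generate_peptide_table()] or [load_peptide_table()]).
#'   A protein present in one table only is treated as count 0 in the other.
#' @param pseudocount added to both counts before forming indices
#'   (0 disables).
#' @param ratio_cutoff proteins with `ratio >= ratio_cutoff` are flagged as
#'   candidates. The threshold is a screening choice, not a fixed constant;
#'   the default of 3 is conventional for spectral-count screens.
#' @param total_mode how "total protein content in the sample" is measured:
#'   `"counts"` (sum of peptide counts; default) or `"mass"`
#'   (sum of count * MW).
#' @return Data frame sorted by descending ratio with columns
#'   `protein_id`, `mw_kda`, `count_bait`, `count_mock`,
#'   `abundance_index_bait`, `abundance_index_mock`, `ratio`, `candidate`.
#' @export
enrichment_screen <- function(bait, mock, pseudocount = 1,
                              ratio_cutoff = 3,
                              total_mode = c("counts", "mass")) {
  total_mode <- match.arg(total_mode)
  if (nrow(bait) == 0L || nrow(mock) == 0L)
    stop("both tables must be non-empty", call. = FALSE)
  stop_if_not_scalar_num(pseudocount, "pseudocount", nonneg = TRUE)
  for (tab in list(bait, mock)) {
    if (anyDuplicated(tab$protein_id))
      stop("duplicate protein ids within a sample", call. = FALSE)
    if (any(tab$count < 0) || any(tab$mw_kda <= 0))
      stop("counts must be >= 0 and MW > 0", call. = FALSE)
  }
  ids <- union(bait$protein_id, mock$protein_id)
  bi <- match(ids, bait$protein_id)
  mi <- match(ids, mock$protein_id)
  mw_b <- bait$mw_kda[bi]
  mw_m <- mock$mw_kda[mi]
  both <- !is.na(bi) & !is.na(mi)
  if (any(both & abs(mw_b - mw_m) > 1e-9 * pmax(1, mw_m), na.rm = TRUE))
    stop("inconsistent molecular weight across tables", call. = FALSE)
  mw <- ifelse(is.na(mw_b), mw_m, mw_b)
  cb <- ifelse(is.na(bi), 0, bait$count[bi])
  cm <- ifelse(is.na(mi), 0, mock$count[mi])
  keep <- cb + cm > 0
  ids <- ids[keep]; mw <- mw[keep]; cb <- cb[keep]; cm <- cm[keep]
  if (length(ids) == 0L)
    stop("no protein observed in either sample", call. = FALSE)
  tot <- function(counts, mws)
    if (total_mode == "counts") sum(counts) else sum(counts * mws)
  total_b <- tot(cb, mw)
  total_m <- tot(cm, mw)
  if (total_b == 0 || total_m == 0)
    stop("a sample has zero total counts", call. = FALSE)
  ai_b <- abundance_index(cb + pseudocount, total_b, mw)
  ai_m <- abundance_index(cm + pseudocount, total_m, mw)
  out <- data.frame(protein_id = ids, mw_kda = mw, count_bait = cb,
                    count_mock = cm, abundance_index_bait = ai_b,
                    abundance_index_mock = ai_m, ratio = ai_b / ai_m)
  out$candidate <- out$ratio >= ratio_cutoff
  out[order(-out$ratio), , drop = FALSE]
}
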
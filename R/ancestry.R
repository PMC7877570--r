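#' Global ancestry from posterior-filtered local tracts
#'
#' Per-individual ancestry proportions are obtained by summing the genetic
#' length (cM) of local-ancestry tracts per ancestry over both haplotypes,
#' after excluding tracts whose posterior probability falls below
#' `min_posterior` (default 0.9), then renormalizing so the retained lengths
#' sum to 1. Under a constant-rate map this is equivalent to a basepair
#' tally; genetic length is used because it matches the ancestry-proportion
#' semantics and is invariant to marker density. An individual whose every
#' tract is excluded gets `NA` proportions.
#'
#' @param la a [local_ancestry_set()].
#' @param min_posterior tracts with posterior `< min_posterior` are dropped;
#'   must be in (0, 1]. Use a value of `.Machine$double.eps` (or any value
#'   below the smallest posterior) for an unfiltered tally.
#' @return tibble with column `id` plus one proportion column per ancestry.
#' @export
compute_global_ancestry <- function(la, min_posterior = 0.9) {
  if (!is.numeric(min_posterior) || length(min_posterior) != 1 ||
      min_posterior <= 0 || min_posterior > 1) {
    stop("min_posterior must be in (0, 1]", call. = FALSE)
  }
  tr <- la$tracts
  cm_len <- numeric(nrow(tr))
  for (ch in unique(tr$chrom)) {
    i <- tr$chrom == ch
    cm_len[i] <- bp_to_cm(la$map, ch, tr$epos[i]) -
      bp_to_cm(la$map, ch, tr$spos[i] - 1)
  }
  keep <- tr$posterior >= min_posterior
  anc <- factor(tr$ancestry, levels = la$ancestries)
  ind <- factor(tr$individual, levels = la$individuals)
  tot <- tapply(cm_len * keep, list(ind, anc), sum, default = 0)
  denom <- rowSums(tot)
  prop <- tot / denom
  prop[denom == 0, ] <- NA_real_
  out <- tibble::as_tibble(prop)
  names(out) <- la$ancestries
  dplyr::bind_cols(tibble::tibble(id = la$individuals), out)
}

#' Local ancestry dosage at genomic positions
#'
#' Counts, per individual and position, how many of the two haplotypes are
#' assigned the given ancestry. A haplotype whose covering tract has
#' posterior below `min_posterior` contributes missingness: the individual's
#' dosage at positions covered by that tract is `NA`.
#'
#' @param la a [local_ancestry_set()].
#' @param ancestry ancestry code to count (e.g. `"PNS"`).
#' @param positions tibble with columns `chrom`, `pos`.
#' @param min_posterior posterior filter applied per tract (default 0.9).
#' @return integer matrix individuals x positions with values in
#'   `{0, 1, 2}` or `NA`; column names `chrom:pos`.
#' @export
local_dosage_at <- function(la, ancestry, positions, min_posterior = 0.9) {
  if (!ancestry %in% la$ancestries) {
    stop("unknown ancestry code: ", ancestry, call. = FALSE)
  }
  lens <- map_chrom_lengths(la$map)
  bad <- !as.character(positions$chrom) %in% names(lens) |
    positions$pos < 1 | positions$pos > lens[as.character(positions$chrom)]
  if (any(bad)) {
    stop("position outside any tract at row ", which(bad)[1], call. = FALSE)
  }
  anc <- hap_ancestry_at(la, positions, "ancestry")
  post <- hap_ancestry_at(la, positions, "posterior")
  code <- match(ancestry, la$ancestries)
  d <- matrix(0L, length(la$individuals), nrow(positions))
  for (h in 1:2) {
    hit <- (anc[[h]] == code) * 1L
    hit[post[[h]] < min_posterior] <- NA_integer_
    d <- d + hit
  }
  rownames(d) <- la$individuals
  colnames(d) <- paste0(positions$chrom, ":", positions$pos)
  d
}
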
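#' Build an evenly spaced genetic map
#'
#' A genetic map places loci at centimorgan (cM) positions along chromosomes.
#' `genetic_map()` spreads `n_loci` markers over `n_chr` chromosomes of equal
#' map length, with loci equally spaced from 0 cM to `chr_length` cM on each
#' chromosome. The default dimensions mirror a typical dense biparental rice
#' panel: 1619 bin markers over 12 chromosomes.
#'
#' @param n_loci Total number of loci across all chromosomes.
#' @param n_chr Number of chromosomes; loci are divided as evenly as possible.
#' @param chr_length Map length of each chromosome in centimorgan.
#'
#' @return A tibble with columns `chrom` (integer), `locus` (character id) and
#'   `pos_cm` (numeric, nondecreasing within chromosome).
#' @examples
#' genetic_map(n_loci = 24, n_chr = 3, chr_length = 100)
#' @export
genetic_map <- function(n_loci = 1619, n_chr = 12, chr_length = 150) {
  if (n_loci < 1) abort("`n_loci` must be at least 1.")
  if (n_chr < 1) abort("`n_chr` must be at least 1.")
  if (n_chr > n_loci) abort("`n_chr` cannot exceed `n_loci`.")
  if (chr_length < 0) abort("`chr_length` must be nonnegative.")
  per_chr <- rep(n_loci %/% n_chr, n_chr)
  extra <- n_loci %% n_chr
  if (extra > 0) per_chr[seq_len(extra)] <- per_chr[seq_len(extra)] + 1L
  purrr::map_dfr(seq_len(n_chr), function(ch) {
    k <- per_chr[ch]
    pos <- if (k == 1) 0 else seq(0, chr_length, length.out = k)
    tibble::tibble(
      chrom = as.integer(ch),
      locus = sprintf("c%02d_m%04d", ch, seq_len(k)),
      pos_cm = pos
    )
  })
}

validate_map <- function(map) {
  req <- c("chrom", "locus", "pos_cm")
  if (!all(req %in% names(map))) {
    abort("A genetic map needs columns `chrom`, `locus`, `pos_cm`.")
  }
  if (nrow(map) < 1) abort("Genetic map is empty.")
  if (anyDuplicated(map$locus)) abort("Duplicate locus ids in map.")
  ok <- map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(sorted = !is.unsorted(.data$pos_cm), .groups = "drop")
  if (!all(ok$sorted)) abort("Positions must be nondecreasing within each chromosome.")
  invisible(map)
}

#' Map functions for recombination
#'
#' `haldane_r()` converts a map distance in centimorgan to a single-meiosis
#' recombination fraction under the Haldane (no-interference) map function,
#' r = (1 - exp(-2d/100)) / 2. `ril_discordance()` converts r to the expected
#' genotype discordance between two loci in a recombinant inbred line (RIL)
#' population derived by repeated selfing, R = 2r / (1 + 2r).
#'
#' @param d_cm Map distance in centimorgan (nonnegative).
#' @param r Single-meiosis recombination fraction in `[0, 0.5]`.
#' @return Numeric vector of recombination fractions / discordance rates.
#' @export
haldane_r <- function(d_cm) {
  if (any(d_cm < 0)) abort("Map distances must be nonnegative.")
  (1 - exp(-2 * d_cm / 100)) / 2
}

#' @rdname haldane_r
#' @export
ril_discordance <- function(r) {
  if (any(r < 0 | r > 0.5)) abort("Recombination fractions must lie in [0, 0.5].")
  2 * r / (1 + 2 * r)
}
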
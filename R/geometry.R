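# Expected nanorod lengths from TMV virion geometry.

#' TMV virion geometry constants
#'
#' The TMV helix packages three RNA nucleotides per coat-protein
#' subunit, and the full U1/Vulgare genome of 6,395 nt builds a 300 nm
#' particle of 18 nm external diameter. Rod length is therefore linear
#' in encapsidated RNA length at 300/6395 ~ 0.0469 nm per nucleotide.
#'
#' @param nt_per_subunit nucleotides bound per coat-protein subunit.
#' @param reference_length_nm full virion length in nm.
#' @param reference_nt full genome length in nucleotides.
#' @param rod_width_nm external rod diameter in nm.
#' @return A list of class `tmv_geometry`; also carries `nm_per_nt`.
#' @export
tmv_geometry <- function(nt_per_subunit = 3L, reference_length_nm = 300,
                         reference_nt = 6395L, rod_width_nm = 18) {
  stopifnot(nt_per_subunit > 0, reference_length_nm > 0,
            reference_nt > 0, rod_width_nm > 0)
  structure(list(nt_per_subunit = nt_per_subunit,
                 reference_length_nm = reference_length_nm,
                 reference_nt = reference_nt,
                 rod_width_nm = rod_width_nm,
                 nm_per_nt = reference_length_nm / reference_nt),
            class = "tmv_geometry")
}

#' Expected rod length for an encapsidated RNA
#'
#' @param n_nt RNA length(s) in nucleotides (> 0).
#' @param geom a [tmv_geometry].
#' @return Expected length(s) in nm: `n_nt * reference_length_nm /
#'   reference_nt`.
#' @examples
#' expected_length(6395)  # 300, the full virion
#' expected_length(1045)  # ~49, the ~1 kb subgenomic-RNA rod
#' @export
expected_length <- function(n_nt, geom = tmv_geometry()) {
  if (any(n_nt <= 0)) stop("`n_nt` must be > 0", call. = FALSE)
  n_nt * geom$nm_per_nt
}

#' Length of an end-to-end multimer
#'
#' Rods aggregate end to end; a k-mer of a unit-length rod is simply k
#' times as long (49, 98, 147 nm for the 49 nm monomer).
#'
#' @param k multimer order, integer >= 1.
#' @param unit_length_nm monomer length in nm.
#' @return `k * unit_length_nm`.
#' @examples
#' multimer_length(1:3, 49)  # 49 98 147
#' @export
multimer_length <- function(k, unit_length_nm) {
  if (any(k < 1)) stop("`k` must be >= 1", call. = FALSE)
  k * unit_length_nm
}
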
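#' Load a chromophore extinction table
#'
#' Reads a CSV with columns `wavelength_nm`, `eps_Hb`, `eps_HbO2`, `eps_ICG`
#' (decadic molar extinction, cm^-1 M^-1). Lines starting with `#` are
#' treated as provenance comments. The package ships a synthetic compilation
#' anchored on standard literature tabulations of Hb/HbO2 molar extinction
#' and ICG absorption in plasma.
#'
#' @param path CSV path; defaults to the table shipped with the package.
#' @return A `spectra_table`: data frame with one row per wavelength.
#' @export
load_spectra <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "chromophore_spectra_synthetic.csv",
                        package = "tripai", mustWork = TRUE)
  }
  tab <- utils::read.csv(path, comment.char = "#")
  required <- c("wavelength_nm", "eps_Hb", "eps_HbO2", "eps_ICG")
  if (!all(required %in% names(tab))) {
    stop("spectra table must have columns: ", paste(required, collapse = ", "))
  }
  if (is.unsorted(tab$wavelength_nm, strictly = TRUE)) {
    stop("wavelengths must be strictly ascending")
  }
  if (any(as.matrix(tab[, -1]) < 0)) stop("negative extinction coefficient in table")
  class(tab) <- c("spectra_table", "data.frame")
  tab
}

#' Molar extinction at given wavelengths
#'
#' Linear interpolation within the table's coverage; no extrapolation.
#'
#' @param spectra a `spectra_table`.
#' @param wavelength_nm numeric vector of wavelengths.
#' @param species one of `"Hb"`, `"HbO2"`, `"ICG"`.
#' @return numeric vector of extinction coefficients (cm^-1 M^-1).
#' @export
eps_at <- function(spectra, wavelength_nm, species = c("Hb", "HbO2", "ICG")) {
  species <- match.arg(species)
  w <- spectra$wavelength_nm
  if (any(wavelength_nm < min(w) | wavelength_nm > max(w))) {
    stop("wavelength outside spectra coverage [", min(w), ", ", max(w), "] nm")
  }
  stats::approx(w, spectra[[paste0("eps_", species)]], xout = wavelength_nm)$y
}

#' Build the spectral system matrix M
#'
#' Each row is one species' extinction spectrum sampled at the requested
#' wavelengths, in normalized (relative) absorption units, the form used by
#' pseudo-inverse unmixing. The default `"global"` normalization divides
#' the whole matrix by one constant (its largest entry), which keeps all
#' species on a common extinction scale — required for the unmixed Hb/HbO2
#' ratio (and hence sO2) to be meaningful, and preserving the Hb/HbO2
#' equality at the 796 nm isosbestic point. `"row_max"` rescales each row
#' to unit maximum instead (shape-only use; per-species scales are then
#' arbitrary). Requires at least as many wavelengths as species and full
#' row rank.
#'
#' @param spectra a `spectra_table`.
#' @param wavelengths_nm wavelengths (nm), ascending.
#' @param species character vector of species names (subset of Hb, HbO2, ICG).
#' @param normalize `"global"` (default) or `"row_max"`.
#' @return an `n_species x n_wavelengths` matrix with dimnames.
#' @export
build_M <- function(spectra, wavelengths_nm,
                    species = c("Hb", "HbO2", "ICG"),
                    normalize = c("global", "row_max")) {
  normalize <- match.arg(normalize)
  if (length(wavelengths_nm) < length(species)) {
    stop("need at least as many wavelengths (", length(wavelengths_nm),
         ") as species (", length(species), ")")
  }
  M <- t(vapply(species, function(sp) {
    row <- eps_at(spectra, wavelengths_nm, sp)
    if (normalize == "row_max") row / max(row) else row
  }, numeric(length(wavelengths_nm))))
  if (normalize == "global") M <- M / max(M)
  dimnames(M) <- list(species, paste0(wavelengths_nm, "nm"))
  qrM <- qr(t(M))
  if (qrM$rank < length(species)) {
    dropped <- species[setdiff(seq_along(species), sort(qrM$pivot[seq_len(qrM$rank)]))]
    stop("spectral matrix is rank deficient; collinear species: ",
         paste(dropped, collapse = ", "))
  }
  M
}
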
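# Lipid annotation against a bundled (or user-supplied) table, and
# fragment/parent image correlation for MS/MS-supported identifications.

#' Load a lipid annotation table
#'
#' Reads a CSV with columns `name, formula, adduct, polarity, role` and
#' precomputes theoretical m/z at both nominal and monoisotopic scale.
#' `role` is either `"ion"` (an annotatable species) or `"loss"` (a neutral
#' loss used in MS/MS interpretation). The package ships a small table
#' covering the acylcarnitines, PI(38:4) and the trimethylamine loss.
#'
#' @param path CSV path; default the bundled table.
#' @return A data.frame with added columns `mz_nominal` and `mz_mono`
#'   (NA for `role == "loss"` rows, whose neutral masses are used instead).
#' @export
load_annotation_table <- function(path = system.file("extdata",
                                                     "lipid_annotations.csv",
                                                     package = "desi3d")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("name", "formula", "adduct", "polarity", "role")
  if (!all(needed %in% names(tab))) {
    stop("annotation table must have columns: ", paste(needed, collapse = ", "))
  }
  tab$mz_nominal <- NA_real_
  tab$mz_mono <- NA_real_
  ion <- tab$role == "ion"
  for (i in which(ion)) {
    tab$mz_nominal[i] <- theoretical_mz(tab$formula[i], tab$adduct[i], "nominal")
    tab$mz_mono[i] <- theoretical_mz(tab$formula[i], tab$adduct[i], "monoisotopic")
    pol <- adduct_polarity(tab$adduct[i])
    if (!identical(pol, tab$polarity[i])) {
      stop("adduct ", tab$adduct[i], " is ", pol,
           " but table row '", tab$name[i], "' declares ", tab$polarity[i])
    }
  }
  tab
}

#' Annotate picked peaks by exact mass
#'
#' Matches observed peak m/z values against an annotation table at
#' monoisotopic scale within a ppm tolerance, gated on polarity. Every
#' match is flagged `"tentative"`: mass-only evidence, mirroring the
#' practice of reporting database matches without fragmentation support
#' as tentative identifications.
#'
#' @param peaks Data.frame with columns `mz` (and optionally `intensity`),
#'   or a numeric vector of m/z values.
#' @param table Annotation table from [load_annotation_table()].
#' @param polarity `"positive"` or `"negative"`; only table entries of this
#'   polarity are considered.
#' @param tolerance_ppm Maximum |mass error| in ppm (default 20, a
#'   Q-TOF-appropriate window).
#' @return Data.frame of matches sorted by |ppm|: `mz_observed, name,
#'   formula, adduct, mz_theoretical, ppm_error, confidence`. Unmatched
#'   peaks are omitted; empty table gives an empty result.
#' @export
annotate_peaks <- function(peaks, table, polarity = c("positive", "negative"),
                           tolerance_ppm = 20) {
  polarity <- match.arg(polarity)
  if (!is.numeric(tolerance_ppm) || tolerance_ppm <= 0) {
    stop("tolerance_ppm must be > 0")
  }
  if (is.numeric(peaks)) peaks <- data.frame(mz = peaks)
  empty <- data.frame(mz_observed = numeric(), name = character(),
                      formula = character(), adduct = character(),
                      mz_theoretical = numeric(), ppm_error = numeric(),
                      confidence = character(), stringsAsFactors = FALSE)
  cand <- table[table$role == "ion" & table$polarity == polarity, , drop = FALSE]
  if (nrow(cand) == 0L || nrow(peaks) == 0L) return(empty)
  out <- empty
  for (i in seq_len(nrow(peaks))) {
    ppm <- (peaks$mz[i] - cand$mz_mono) / cand$mz_mono * 1e6
    hit <- which(abs(ppm) <= tolerance_ppm)
    if (length(hit)) {
      out <- rbind(out, data.frame(
        mz_observed = peaks$mz[i], name = cand$name[hit],
        formula = cand$formula[hit], adduct = cand$adduct[hit],
        mz_theoretical = cand$mz_mono[hit], ppm_error = ppm[hit],
        confidence = "tentative", stringsAsFactors = FALSE))
    }
  }
  out[order(abs(out$ppm_error)), , drop = FALSE]
}

#' Fragment/parent ion-image correlation
#'
#' Pearson correlation between a parent ion image and an MS/MS fragment
#' ion image over tissue pixels, quantifying whether the fragment
#' co-localises with its parent (supporting the structural assignment).
#'
#' @param parent,fragment Numeric matrices of the same shape.
#' @param tissue_mask Logical matrix of the same shape; only TRUE pixels
#'   enter the correlation. Default: all pixels.
#' @return Pearson r.
#' @export
fragment_parent_coloc <- function(parent, fragment, tissue_mask = NULL) {
  stopifnot(is.matrix(parent), is.matrix(fragment),
            all(dim(parent) == dim(fragment)))
  if (is.null(tissue_mask)) tissue_mask <- matrix(TRUE, nrow(parent), ncol(parent))
  stopifnot(all(dim(tissue_mask) == dim(parent)))
  p <- parent[tissue_mask]; f <- fragment[tissue_mask]
  if (length(p) < 3L) stop("need at least 3 tissue pixels")
  if (stats::sd(p) == 0 || stats::sd(f) == 0) {
    stop("correlation undefined: constant image over tissue pixels")
  }
  stats::cor(p, f)
}
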
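#' MAG quality-control thresholds
#'
#' Defaults follow the MIMAG high-quality standard plus an assembly
#' contiguity requirement: completeness >= 90%, contamination <= 5%,
#' >= 18 tRNA genes, presence of the 5S, 16S and 23S rRNA classes, and
#' N50 >= 100 kb. All thresholds are inclusive.
#'
#' @param min_completeness minimum completeness (%).
#' @param max_contamination maximum contamination/redundancy (%).
#' @param min_trna minimum tRNA gene count.
#' @param required_rrna character vector of rRNA classes that must all be
#'   present; set to `character(0)` (or a subset) to relax.
#' @param min_n50 minimum N50 (bp).
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_completeness = 90, max_contamination = 5,
                          min_trna = 18,
                          required_rrna = c("5S", "16S", "23S"),
                          min_n50 = 1e5) {
  stopifnot(min_completeness >= 0, max_contamination >= 0,
            min_trna >= 0, min_n50 >= 0)
  structure(list(min_completeness = min_completeness,
                 max_contamination = max_contamination,
                 min_trna = min_trna,
                 required_rrna = required_rrna,
                 min_n50 = min_n50),
            class = "qc_thresholds")
}

#' Compute assembly N50
#'
#' N50 is the contig length L such that contigs of length >= L (taken in
#' descending order) cumulatively cover at least half of the assembly.
#'
#' @param contig_lengths numeric vector of contig lengths (bp).
#' @return N50 in bp.
#' @export
compute_n50 <- function(contig_lengths) {
  if (length(contig_lengths) == 0) stop("empty contig length list")
  if (any(contig_lengths <= 0)) stop("contig lengths must be positive")
  len <- sort(contig_lengths, decreasing = TRUE)
  len[which(cumsum(len) >= sum(len) / 2)[1]]
}

#' MIMAG-style quality gate for one MAG
#'
#' @param mag a one-row data.frame or list with fields `completeness`,
#'   `contamination`, `trna_count`, `rrna_classes` (comma-separated string
#'   or character vector) and `n50`.
#' @param thresholds a [qc_thresholds()] object.
#' @return list with logical `pass` and character `failed` naming the
#'   violated criteria (empty when passing).
#' @export
mimag_filter <- function(mag, thresholds = qc_thresholds()) {
  need <- c("completeness", "contamination", "trna_count", "rrna_classes",
            "n50")
  for (f in need) {
    v <- mag[[f]]
    if (is.null(v) || (f != "rrna_classes" && (length(v) != 1 || is.na(v))))
      stop("MAG record missing metadata field: ", f)
  }
  rrna <- mag[["rrna_classes"]]
  if (is.character(rrna) && length(rrna) == 1)
    rrna <- strsplit(rrna, ",", fixed = TRUE)[[1]]
  rrna <- trimws(rrna)
  failed <- character(0)
  if (mag$completeness < thresholds$min_completeness)
    failed <- c(failed, "completeness")
  if (mag$contamination > thresholds$max_contamination)
    failed <- c(failed, "contamination")
  if (mag$trna_count < thresholds$min_trna)
    failed <- c(failed, "trna_count")
  if (!all(thresholds$required_rrna %in% rrna))
    failed <- c(failed, "rrna_classes")
  if (mag$n50 < thresholds$min_n50)
    failed <- c(failed, "n50")
  list(pass = length(failed) == 0, failed = failed)
}

#' Apply the MIMAG gate to a cohort of MAGs
#'
#' @param mags MAG metadata data.frame (see [read_mag_metadata()]).
#' @param thresholds a [qc_thresholds()] object.
#' @return data.frame with `mag_id`, logical `pass`, and `failed`
#'   (comma-separated criteria).
#' @export
qc_cohort <- function(mags, thresholds = qc_thresholds()) {
  res <- lapply(seq_len(nrow(mags)), function(i)
    mimag_filter(mags[i, , drop = FALSE], thresholds))
  data.frame(
    mag_id = mags$mag_id,
    pass = vapply(res, `[[`, logical(1), "pass"),
    failed = vapply(res, function(r) paste(r$failed, collapse = ","),
                    character(1)),
    stringsAsFactors = FALSE)
}
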
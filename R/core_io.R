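#' @importFrom utils read.delim write.table head
NULL

.MGE_CLASSES <- c("plasmid", "prophage", "ICE_IME", "integron")
.VAR_TYPES <- c("SNP_synonymous", "SNP_nonsynonymous", "SNP_unclassified",
                "indel")

# Skip leading comment lines (writers emit a commented header stating column
# semantics) and read a TSV with character columns.
.read_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) == 0) stop("no content in ", path)
  read.delim(text = paste(lines, collapse = "\n"), sep = "\t",
             header = TRUE, colClasses = "character",
             check.names = FALSE, na.strings = c("NA", ""))
}

.write_tsv <- function(df, path, comment) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", comment), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
}

#' Assign per-contig gene ordinals
#'
#' Orders genes within each contig by ascending start (ties broken by
#' ascending end, then lexicographic gene id) and assigns 0-based ordinals.
#' The ordinal is the gene-order coordinate used by all gap rules
#' (system assembly, island calling, pair colocalization).
#'
#' @param genes data.frame with columns `mag_id`, `contig_id`, `gene_id`,
#'   `start`, `end`, `strand`.
#' @return The same data.frame, row-ordered by (mag, contig, ordinal), with
#'   an integer `ordinal` column added.
#' @export
assign_ordinals <- function(genes) {
  key <- paste(genes$mag_id, genes$contig_id, sep = "\r")
  o <- order(key, genes$start, genes$end, genes$gene_id)
  genes <- genes[o, , drop = FALSE]
  key <- key[o]
  genes$ordinal <- as.integer(
    stats::ave(seq_along(key), key, FUN = seq_along) - 1L)
  rownames(genes) <- NULL
  genes
}

.validate_genes <- function(genes, where = "gene table") {
  bad <- which(genes$end < genes$start)
  if (length(bad) > 0)
    stop(where, ": end < start at row(s) ", paste(head(bad, 5), collapse = ","))
  if (any(genes$start < 1))
    stop(where, ": start coordinates must be >= 1 (1-based inclusive)")
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0)
    stop(where, ": duplicate gene_id: ", paste(unique(head(dup, 5)),
                                               collapse = ","))
  if (!all(genes$strand %in% c("+", "-")))
    stop(where, ": strand must be '+' or '-'")
  invisible(genes)
}

#' Read a gene table (GFF3 or TSV)
#'
#' TSV input must carry the header
#' `mag_id, contig_id, gene_id, start, end, strand` (1-based inclusive
#' coordinates). GFF3 input is parsed with \pkg{rtracklayer}; rows of type
#' `CDS` or `gene` are kept, the `ID` attribute is the gene id and the file
#' name (without extension) is used as the MAG id.
#'
#' @param path path to a `.gff`/`.gff3` or TSV file.
#' @param mag_id MAG identifier to use for GFF3 input; defaults to the file
#'   name without extension.
#' @return data.frame of genes with per-contig ordinals (see
#'   [assign_ordinals()]).
#' @export
read_gene_table <- function(path, mag_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path)
    df <- as.data.frame(gr)
    df <- df[df$type %in% c("CDS", "gene"), , drop = FALSE]
    if (is.null(mag_id))
      mag_id <- sub("\\.gff3?$", "", basename(path), ignore.case = TRUE)
    id <- if ("ID" %in% names(df)) as.character(df$ID) else NA_character_
    if (anyNA(id)) stop("GFF3 rows without an ID attribute in ", path)
    genes <- data.frame(
      mag_id = mag_id,
      contig_id = as.character(df$seqnames),
      gene_id = id,
      start = as.integer(df$start),
      end = as.integer(df$end),
      strand = as.character(df$strand),
      stringsAsFactors = FALSE)
  } else {
    raw <- .read_tsv(path)
    need <- c("mag_id", "contig_id", "gene_id", "start", "end", "strand")
    miss <- setdiff(need, names(raw))
    if (length(miss) > 0)
      stop("gene table ", path, " lacks column(s): ",
           paste(miss, collapse = ","))
    start <- suppressWarnings(as.integer(raw$start))
    end <- suppressWarnings(as.integer(raw$end))
    bad <- which(is.na(start) | is.na(end))
    if (length(bad) > 0)
      stop("malformed gene table row (non-numeric coordinates) at data line ",
           bad[1], " of ", path)
    genes <- data.frame(
      mag_id = raw$mag_id, contig_id = raw$contig_id,
      gene_id = raw$gene_id, start = start, end = end,
      strand = raw$strand, stringsAsFactors = FALSE)
  }
  .validate_genes(genes, where = path)
  assign_ordinals(genes)
}

#' Write a gene table as TSV
#'
#' @param genes gene data.frame.
#' @param path output path.
#' @export
write_gene_table <- function(genes, path) {
  cols <- c("mag_id", "contig_id", "gene_id", "start", "end", "strand")
  .write_tsv(genes[, cols],
             path,
             "gene table: start/end are bp, 1-based inclusive; strand +/-")
  invisible(path)
}

#' Read defense-gene annotations (DefenseFinder-style TSV)
#'
#' Expects columns `gene_id`, `family`, `gene_name`, `role`
#' (mandatory/accessory, case-insensitive) and optionally `system_id`.
#' If a gene id appears more than once the first row wins and a warning
#' reports the number of duplicates dropped.
#'
#' @param path TSV path.
#' @return data.frame with one annotation per gene id.
#' @export
read_defense_annotations <- function(path) {
  raw <- .read_tsv(path)
  need <- c("gene_id", "family", "gene_name", "role")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0)
    stop("defense annotation table lacks column(s): ",
         paste(miss, collapse = ","))
  if (anyNA(raw$family) || any(raw$family == ""))
    stop("defense annotation with missing family")
  role <- tolower(raw$role)
  bad <- setdiff(unique(role), c("mandatory", "accessory"))
  if (length(bad) > 0)
    stop("unknown role value(s): ", paste(bad, collapse = ","),
         " (allowed: mandatory, accessory)")
  hits <- data.frame(
    gene_id = raw$gene_id, family = raw$family,
    gene_name = raw$gene_name, role = role,
    system_id = if ("system_id" %in% names(raw)) raw$system_id
                else NA_character_,
    stringsAsFactors = FALSE)
  dup <- duplicated(hits$gene_id)
  if (any(dup)) {
    warning(sum(dup), " duplicate defense hit(s) dropped (first row kept)")
    hits <- hits[!dup, , drop = FALSE]
  }
  rownames(hits) <- NULL
  hits
}

#' Write defense-gene annotations as TSV
#' @param hits annotation data.frame.
#' @param path output path.
#' @export
write_defense_annotations <- function(hits, path) {
  cols <- c("gene_id", "family", "gene_name", "role", "system_id")
  .write_tsv(hits[, cols], path,
             "defense annotations: role in {mandatory,accessory}")
  invisible(path)
}

#' Resolve conflicting MGE intervals
#'
#' Same-class overlapping or nested intervals are merged by union; any
#' interval overlapping (>= 1 bp) an interval of a *different* class is then
#' removed together with its partner, mirroring the exclusion of MGE hits
#' matching multiple element families. The number of removed intervals is
#' reported via `message()`.
#'
#' @param mge data.frame with `contig_id`, `start`, `end` (1-based
#'   inclusive), `mge_class`.
#' @return conflict-free data.frame of intervals.
#' @export
resolve_mge_conflicts <- function(mge) {
  if (nrow(mge) == 0) return(mge)
  bad <- setdiff(unique(mge$mge_class), .MGE_CLASSES)
  if (length(bad) > 0)
    stop("unknown MGE class label(s): ", paste(bad, collapse = ","),
         " (allowed: ", paste(.MGE_CLASSES, collapse = ","), ")")
  if (any(mge$end < mge$start)) stop("MGE interval with end < start")
  merged <- do.call(rbind, lapply(
    split(mge, list(mge$contig_id, mge$mge_class), drop = TRUE),
    function(d) {
      ir <- IRanges::reduce(IRanges::IRanges(d$start, d$end))
      data.frame(contig_id = d$contig_id[1],
                 start = IRanges::start(ir), end = IRanges::end(ir),
                 mge_class = d$mge_class[1], stringsAsFactors = FALSE)
    }))
  rownames(merged) <- NULL
  drop <- logical(nrow(merged))
  for (ctg in unique(merged$contig_id)) {
    idx <- which(merged$contig_id == ctg)
    ir <- IRanges::IRanges(merged$start[idx], merged$end[idx])
    ov <- IRanges::findOverlaps(ir, ir)
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    cross <- merged$mge_class[idx[qh]] != merged$mge_class[idx[sh]]
    drop[idx[unique(c(qh[cross], sh[cross]))]] <- TRUE
  }
  if (any(drop))
    message(sum(drop), " MGE interval(s) removed for multi-class overlap")
  out <- merged[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read MGE intervals from BED
#'
#' BED is 0-based half-open; coordinates are converted to the package's
#' 1-based inclusive convention. Column 4 must carry the element class
#' (plasmid, prophage, ICE_IME, integron). Conflicting intervals are
#' resolved with [resolve_mge_conflicts()].
#'
#' @param path BED path.
#' @return data.frame of conflict-filtered intervals.
#' @export
read_mge_intervals <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- as.data.frame(gr)
  if (!"name" %in% names(df))
    stop("BED file lacks a name (class) column: ", path)
  mge <- data.frame(
    contig_id = as.character(df$seqnames),
    start = as.integer(df$start),  # rtracklayer already 1-based inclusive
    end = as.integer(df$end),
    mge_class = as.character(df$name),
    stringsAsFactors = FALSE)
  resolve_mge_conflicts(mge)
}

#' Write MGE intervals as BED (0-based half-open)
#' @param mge interval data.frame (1-based inclusive).
#' @param path output path.
#' @export
write_mge_bed <- function(mge, path) {
  bed <- data.frame(chrom = mge$contig_id,
                    chromStart = mge$start - 1L,
                    chromEnd = mge$end,
                    name = mge$mge_class)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read variant records (VCF or TSV)
#'
#' VCF input (via \pkg{vcfR}) yields one record per alternate allele; the
#' CHROM field is interpreted as the analyzed-region (gene) id and POS as
#' the 1-based position within that region. Allele frequency is taken from
#' AF, or computed as AO/DP when AF is absent; records with DP = 0 are
#' skipped with a warning. TSV input must carry columns `gene_id`,
#' `position`, `var_type`, `region`, `allele_frequency`,
#' `supporting_reads` (as written by [write_variants()]).
#'
#' @param path VCF (`.vcf`) or TSV path.
#' @return data.frame of variant records.
#' @export
read_variants <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, "DP")))
    ao <- vcfR::extract.info(v, "AO")
    af <- vcfR::extract.info(v, "AF")
    out <- list()
    skipped <- 0L
    for (i in seq_len(nrow(fix))) {
      alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
      if (is.na(dp[i]) || dp[i] <= 0) {
        skipped <- skipped + 1L
        next
      }
      aos <- if (!is.na(ao[i]))
        suppressWarnings(as.numeric(strsplit(ao[i], ",")[[1]]))
      else rep(NA_real_, length(alts))
      afs <- if (!is.na(af[i]))
        suppressWarnings(as.numeric(strsplit(af[i], ",")[[1]]))
      else aos / dp[i]
      for (k in seq_along(alts)) {
        reads <- if (!is.na(aos[k])) aos[k] else round(afs[k] * dp[i])
        out[[length(out) + 1L]] <- data.frame(
          gene_id = fix$CHROM[i],
          position = as.integer(fix$POS[i]),
          ref = fix$REF[i], alt = alts[k],
          var_type = if (nchar(fix$REF[i]) != nchar(alts[k])) "indel"
                     else "SNP_unclassified",
          region = NA_character_,
          allele_frequency = afs[k],
          supporting_reads = as.integer(reads),
          stringsAsFactors = FALSE)
      }
    }
    if (skipped > 0)
      warning(skipped, " VCF record(s) with DP=0 skipped")
    vars <- if (length(out) > 0) do.call(rbind, out) else
      data.frame(gene_id = character(0), position = integer(0),
                 ref = character(0), alt = character(0),
                 var_type = character(0), region = character(0),
                 allele_frequency = numeric(0),
                 supporting_reads = integer(0))
  } else {
    raw <- .read_tsv(path)
    need <- c("gene_id", "position", "var_type", "region",
              "allele_frequency", "supporting_reads")
    miss <- setdiff(need, names(raw))
    if (length(miss) > 0)
      stop("variant table lacks column(s): ", paste(miss, collapse = ","))
    vars <- data.frame(
      gene_id = raw$gene_id,
      position = as.integer(raw$position),
      ref = if ("ref" %in% names(raw)) raw$ref else NA_character_,
      alt = if ("alt" %in% names(raw)) raw$alt else NA_character_,
      var_type = raw$var_type,
      region = raw$region,
      allele_frequency = as.numeric(raw$allele_frequency),
      supporting_reads = as.integer(raw$supporting_reads),
      stringsAsFactors = FALSE)
  }
  if (any(vars$allele_frequency < 0 | vars$allele_frequency > 1,
          na.rm = TRUE))
    stop("allele frequency outside [0,1] in ", path)
  if (any(vars$supporting_reads < 0, na.rm = TRUE))
    stop("negative supporting read count in ", path)
  rownames(vars) <- NULL
  vars
}

#' Write variant records as TSV
#' @param vars variant data.frame.
#' @param path output path.
#' @export
write_variants <- function(vars, path) {
  cols <- c("gene_id", "position", "ref", "alt", "var_type", "region",
            "allele_frequency", "supporting_reads")
  for (cc in setdiff(cols, names(vars))) vars[[cc]] <- NA
  .write_tsv(vars[, cols], path, paste(
    "variants: position 1-based within analyzed region;",
    "allele_frequency in [0,1]; supporting_reads = alt-supporting reads"))
  invisible(path)
}

#' Read MAG metadata
#'
#' TSV with columns `mag_id`, `habitat`, `size_bp`, `completeness`,
#' `contamination`, `trna_count`, `rrna_classes` (comma-separated subset of
#' 5S,16S,23S) and either `n50` or `contig_lengths` (comma-separated bp).
#'
#' @param path TSV path.
#' @return data.frame of MAG records; `n50` is computed from
#'   `contig_lengths` when absent.
#' @export
read_mag_metadata <- function(path) {
  raw <- .read_tsv(path)
  need <- c("mag_id", "habitat", "size_bp", "completeness", "contamination",
            "trna_count", "rrna_classes")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0)
    stop("MAG metadata lacks column(s): ", paste(miss, collapse = ","))
  mags <- data.frame(
    mag_id = raw$mag_id, habitat = raw$habitat,
    size_bp = as.numeric(raw$size_bp),
    completeness = as.numeric(raw$completeness),
    contamination = as.numeric(raw$contamination),
    trna_count = as.integer(raw$trna_count),
    rrna_classes = raw$rrna_classes,
    stringsAsFactors = FALSE)
  if ("n50" %in% names(raw)) {
    mags$n50 <- as.numeric(raw$n50)
  } else if ("contig_lengths" %in% names(raw)) {
    mags$n50 <- vapply(strsplit(raw$contig_lengths, ","), function(x)
      compute_n50(as.numeric(x)), numeric(1))
  } else {
    stop("MAG metadata needs an n50 or contig_lengths column")
  }
  mags
}

#' Write MAG metadata as TSV
#' @param mags MAG data.frame.
#' @param path output path.
#' @export
write_mag_metadata <- function(mags, path) {
  cols <- c("mag_id", "habitat", "size_bp", "completeness", "contamination",
            "trna_count", "rrna_classes", "n50")
  .write_tsv(mags[, cols], path, paste(
    "MAG metadata: completeness/contamination in %, size_bp/n50 in bp,",
    "rrna_classes comma-separated subset of 5S,16S,23S"))
  invisible(path)
}
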
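#' Read a MatrixMarket count matrix with gene and barcode sidecars
#'
#' Reads 10x-style triplets (matrix.mtx, features/genes TSV, barcodes TSV) into
#' a [count_matrix()]. The internal orientation is genes x cells; a cells x
#' genes MTX is transposed automatically when the barcode count matches the
#' row dimension. Malformed input (dimension mismatch, duplicate barcodes,
#' negative or fractional entries) is rejected rather than coerced.
#'
#' @param mtx_path path to the MatrixMarket file.
#' @param features_path path to a header-less TSV whose first column holds
#'   gene symbols.
#' @param barcodes_path path to a header-less single-column TSV of barcodes.
#' @return a `CountMatrix`.
#' @export
read_counts <- function(mtx_path, features_path, barcodes_path) {
  for (p in c(mtx_path, features_path, barcodes_path))
    if (!file.exists(p)) stop("read_counts: file not found: ", p)
  m <- Matrix::readMM(mtx_path)
  feats <- utils::read.table(features_path, sep = "\t", header = FALSE,
                             colClasses = "character", quote = "")[[1]]
  bcs <- utils::read.table(barcodes_path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "")[[1]]
  dupb <- bcs[duplicated(bcs)]
  if (length(dupb))
    stop("read_counts: duplicate barcode(s): ", paste(unique(dupb), collapse = ", "))
  if (nrow(m) == length(feats) && ncol(m) == length(bcs)) {
    # genes x cells as stored
  } else if (nrow(m) == length(bcs) && ncol(m) == length(feats)) {
    m <- Matrix::t(m)
  } else {
    stop(sprintf(
      "read_counts: matrix is %d x %d but %d features / %d barcodes given",
      nrow(m), ncol(m), length(feats), length(bcs)))
  }
  count_matrix(m, feats, bcs)
}

#' Write a CountMatrix as MatrixMarket triplets
#'
#' @param cm a `CountMatrix`.
#' @param dir output directory (created if missing).
#' @return invisibly, the three file paths written.
#' @export
write_counts <- function(cm, dir) {
  stopifnot(inherits(cm, "CountMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  Matrix::writeMM(cm$counts, paths[1])
  writeLines(cm$genes, paths[2])
  writeLines(cm$cells, paths[3])
  invisible(paths)
}

VALID_CHAINS <- c("TRA", "TRB", "TRG", "TRD")
CDR3_RE <- "^[ACDEFGHIKLMNPQRSTVWY]+$"

#' Read a 10x-style VDJ contig annotation table
#'
#' Keeps productive contigs with a usable CDR3 amino-acid sequence on a TCR
#' chain. Rows with `productive` other than `True`/`true`/`TRUE` (or logical
#' `TRUE`), or a CDR3 of `NA`/`""`/`"None"`, are dropped silently (that is the
#' 10x convention for uncalled contigs); rows on chains outside
#' TRA/TRB/TRG/TRD, or with non-amino-acid CDR3 characters, are dropped with
#' a warning.
#'
#' @param csv_path path to a CSV with columns `barcode`, `chain`, `cdr3`,
#'   `productive`, `umis` (extra columns are ignored).
#' @return a data.frame with columns `cell_id`, `chain`, `cdr3_aa`,
#'   `productive`, `umis`.
#' @export
read_contigs <- function(csv_path) {
  if (!file.exists(csv_path)) stop("read_contigs: file not found: ", csv_path)
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("barcode", "chain", "cdr3", "productive", "umis")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_contigs: missing required column(s): ", paste(miss, collapse = ", "))
  prod <- df$productive %in% c("True", "true", "TRUE")
  cdr3 <- df$cdr3
  usable <- prod & !is.na(cdr3) & !(cdr3 %in% c("", "None"))
  df <- df[usable, , drop = FALSE]
  bad_chain <- !(df$chain %in% VALID_CHAINS)
  if (any(bad_chain)) {
    warning("read_contigs: dropping ", sum(bad_chain),
            " contig(s) on unsupported chain(s): ",
            paste(unique(df$chain[bad_chain]), collapse = ", "))
    df <- df[!bad_chain, , drop = FALSE]
  }
  bad_aa <- !grepl(CDR3_RE, df$cdr3)
  if (any(bad_aa)) {
    warning("read_contigs: dropping ", sum(bad_aa),
            " contig(s) with non-amino-acid CDR3 characters")
    df <- df[!bad_aa, , drop = FALSE]
  }
  umis <- suppressWarnings(as.numeric(df$umis))
  if (any(is.na(umis) | umis < 0 | umis != round(umis)))
    stop("read_contigs: umis must be non-negative integers")
  out <- data.frame(cell_id = df$barcode, chain = df$chain, cdr3_aa = df$cdr3,
                    productive = TRUE, umis = as.integer(umis),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a contig table in the 10x 5-column dialect
#' @param contigs data.frame as returned by [read_contigs()].
#' @param path output CSV path.
#' @export
write_contigs <- function(contigs, path) {
  out <- data.frame(barcode = contigs$cell_id, chain = contigs$chain,
                    cdr3 = contigs$cdr3_aa,
                    productive = ifelse(contigs$productive, "True", "False"),
                    umis = contigs$umis)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a records table as TSV or JSON
#'
#' Floats are serialized with 10 significant digits so that
#' `read_table(write_table(x))` round-trips losslessly for practical
#' purposes. An empty data.frame yields a header-only file.
#'
#' @param records a data.frame.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_table <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(records))
  if (format == "json") {
    jsonlite::write_json(records, path, digits = 10, na = "null")
    return(invisible(path))
  }
  out <- records
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- signif_chr(out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

signif_chr <- function(x) {
  s <- formatC(x, digits = 10, format = "g")
  s[is.na(x)] <- "NA"
  trimws(s)
}

#' Read back a table written by [write_table()]
#' @param path input path.
#' @param format `"tsv"` or `"json"`.
#' @return a data.frame.
#' @export
read_table <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_table: file not found: ", path)
  if (format == "json")
    return(as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE)))
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    quote = "")
}

#' Read a flat ligand-receptor pair list
#'
#' @param path TSV with columns `pair_id`, `ligand_gene`, `receptor_gene`.
#' @return a data.frame with those columns; duplicate `pair_id`s are rejected.
#' @export
read_pairs <- function(path) {
  df <- read_table(path, "tsv")
  need <- c("pair_id", "ligand_gene", "receptor_gene")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_pairs: missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$pair_id))
    stop("read_pairs: duplicate pair_id(s)")
  if (any(!nzchar(df$ligand_gene)) || any(!nzchar(df$receptor_gene)))
    stop("read_pairs: empty gene name")
  df$ligand_gene <- toupper(df$ligand_gene)
  df$receptor_gene <- toupper(df$receptor_gene)
  df[, need]
}

#' Read a cell metadata table
#'
#' @param path CSV with columns `cell_id`, `sample_id`, `patient_id`,
#'   `lesion_class`, `cluster`.
#' @return a validated data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("read_metadata: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("cell_id", "sample_id", "patient_id", "lesion_class", "cluster")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_metadata: missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$cell_id))
    stop("read_metadata: duplicate cell_id(s)")
  bad <- setdiff(unique(df$lesion_class), LESION_CLASSES)
  if (length(bad))
    stop("read_metadata: unknown lesion_class value(s): ", paste(bad, collapse = ", "))
  df[, need]
}

#' Recognized lesion-class labels
#' @export
LESION_CLASSES <- c("patch", "plaque", "tumor", "erythroderma",
                    "nonlesional", "healthy", "followup")
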
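# Readers and writers for the four external inputs (OTU counts, taxonomy,
# representative sequences, sample metadata) and the pipeline's TSV outputs.
# All tabular outputs carry the schema comment line "#rtshift:1".

SCHEMA_TAG <- "#rtshift:1"

#' Validate an OTU count matrix
#'
#' Checks the invariants every count table entering the pipeline must satisfy:
#' non-negative integer counts, unique sample and OTU identifiers, at least
#' one sample and one OTU.
#'
#' @param table numeric matrix, samples in rows, OTUs in columns, with
#'   dimnames.
#' @return the validated table with integer storage mode.
#' @export
validate_otu_table <- function(table) {
  if (!is.matrix(table) || nrow(table) < 1L || ncol(table) < 1L)
    stop("OTU table must be a matrix with at least 1 sample and 1 OTU")
  if (is.null(rownames(table)) || is.null(colnames(table)))
    stop("OTU table must have sample ids (rownames) and OTU ids (colnames)")
  if (anyDuplicated(rownames(table)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(table)[duplicated(rownames(table))]), collapse = ", "))
  if (anyDuplicated(colnames(table)))
    stop("duplicate OTU ids: ",
         paste(unique(colnames(table)[duplicated(colnames(table))]), collapse = ", "))
  if (!is.numeric(table))
    stop("OTU table contains non-numeric values")
  bad <- is.na(table) | table < 0 | abs(table - round(table)) > 1e-8
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid count at sample '%s', OTU '%s': %s",
                 rownames(table)[idx[1L]], colnames(table)[idx[2L]],
                 format(table[idx[1L], idx[2L]])))
  }
  storage.mode(table) <- "integer"
  table
}

#' Read an OTU count table
#'
#' @param path path to a tab-delimited table (first column sample ids, header
#'   row OTU ids) or a BIOM-JSON file.
#' @param format `"tsv"` (default) or `"biom"` (dense BIOM-JSON, in which the
#'   canonical orientation is observations x samples and is transposed on
#'   read).
#' @param samples_in_rows for TSV input, set `FALSE` if the file stores OTUs
#'   in rows and samples in columns; the table is transposed after reading.
#' @return integer matrix, samples x OTUs.
#' @export
read_otu_table <- function(path, format = c("tsv", "biom"),
                           samples_in_rows = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    dat <- utils::read.delim(path, header = TRUE, sep = "\t",
                             comment.char = "#", check.names = FALSE,
                             stringsAsFactors = FALSE, quote = "")
    if (ncol(dat) < 2L)
      stop("malformed OTU table: need an id column plus at least one count column")
    m <- as.matrix(dat[, -1L, drop = FALSE])
    if (!is.numeric(m)) {
      # locate the offending cell for the error message
      num <- suppressWarnings(apply(dat[, -1L, drop = FALSE], 2L,
                                    function(x) as.numeric(x)))
      bad <- which(is.na(num) & !is.na(as.matrix(dat[, -1L, drop = FALSE])),
                   arr.ind = TRUE)
      if (length(bad))
        stop(sprintf("non-numeric count at row '%s', column '%s'",
                     dat[[1L]][bad[1L, 1L]], colnames(dat)[-1L][bad[1L, 2L]]))
      m <- num
    }
    rownames(m) <- as.character(dat[[1L]])
    if (!samples_in_rows) m <- t(m)
  } else {
    b <- biomformat::read_biom(path)
    m <- t(as(biomformat::biom_data(b), "matrix"))
  }
  validate_otu_table(m)
}

#' Write an OTU count table as schema-tagged TSV
#'
#' @param table validated count matrix (samples x OTUs).
#' @param path output path.
#' @export
write_otu_table <- function(table, path) {
  table <- validate_otu_table(table)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(SCHEMA_TAG, con)
  df <- data.frame(sample_id = rownames(table), table,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Class rank sits at position 3 of a domain;phylum;class;... lineage.
# QIIME-style rank prefixes ("c__") are tolerated and stripped.
lineage_class <- function(lineage) {
  if (is.na(lineage) || !nzchar(trimws(lineage)))
    stop("empty lineage string")
  fields <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1L]])
  fields <- sub("^[a-zA-Z]__", "", fields)
  if (length(fields) < 1L || !nzchar(fields[1L]))
    stop("empty lineage string")
  if (length(fields) < 3L || !nzchar(fields[3L])) return("Unclassified")
  fields[3L]
}

#' Read an OTU taxonomy table
#'
#' Two tab-separated columns: OTU id and a semicolon-delimited SILVA-style
#' lineage (domain;phylum;class;...). OTUs whose lineage lacks a class rank
#' receive the sentinel label `"Unclassified"`.
#'
#' @param path path to the taxonomy TSV (a header row is tolerated).
#' @return data.frame with columns `otu_id`, `lineage`, `class_label`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dat <- utils::read.delim(path, header = FALSE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           quote = "")
  if (nrow(dat) && tolower(gsub("[#_ ]", "", dat[1L, 1L])) %in%
      c("otuid", "otu")) dat <- dat[-1L, , drop = FALSE]
  if (ncol(dat) < 2L)
    stop("taxonomy file must have two tab-separated columns: otu_id, lineage")
  otu <- as.character(dat[[1L]])
  lineage <- as.character(dat[[2L]])
  if (anyDuplicated(otu))
    stop("duplicate otu_id in taxonomy: ",
         paste(unique(otu[duplicated(otu)]), collapse = ", "))
  cls <- vapply(lineage, lineage_class, character(1L), USE.NAMES = FALSE)
  data.frame(otu_id = otu, lineage = lineage, class_label = cls,
             stringsAsFactors = FALSE)
}

IUPAC_NT <- c("A", "C", "G", "T", "U", "W", "S", "M", "K", "R", "Y",
              "B", "D", "H", "V", "N")

#' Read representative sequences from FASTA
#'
#' Record id is the header token before the first whitespace; sequences are
#' uppercased and restricted to the IUPAC nucleotide alphabet (gap characters
#' are rejected).
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences, one per OTU.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- seqinr::read.fasta(path, as.string = TRUE,
                             forceDNAtolower = FALSE, seqonly = FALSE)
  ids <- vapply(recs, function(x) attr(x, "name"), character(1L))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(vapply(recs, function(x) as.character(x)[1L], character(1L)))
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("empty sequence for record(s): ", paste(ids[empty], collapse = ", "))
  ok <- grepl(paste0("^[", paste(IUPAC_NT, collapse = ""), "]+$"), seqs)
  if (!all(ok))
    stop("non-IUPAC nucleotide character in record(s): ",
         paste(ids[!ok], collapse = ", "))
  names(seqs) <- ids
  seqs
}

#' Write representative sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  seqinr::write.fasta(as.list(seqs), names = names(seqs), file.out = path,
                      nbchar = 80)
  invisible(path)
}

#' Build a condition label from enzyme and temperature
#' @param enzyme enzyme label.
#' @param temperature_c reaction temperature in degrees Celsius.
#' @export
make_condition <- function(enzyme, temperature_c)
  paste(enzyme, temperature_c)

#' Read sample metadata
#'
#' Expects a TSV with header columns `sample_id`, `enzyme`, `temperature_c`,
#' `replicate`. The experimental condition is the (enzyme, temperature) pair.
#'
#' @param path path to the metadata TSV.
#' @return data.frame with columns `sample_id`, `enzyme`, `temperature_c`,
#'   `replicate`, `condition`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dat <- utils::read.delim(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           quote = "")
  req <- c("sample_id", "enzyme", "temperature_c", "replicate")
  miss <- setdiff(req, colnames(dat))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  dat$sample_id <- as.character(dat$sample_id)
  dat$enzyme <- as.character(dat$enzyme)
  dat$replicate <- as.character(dat$replicate)
  dat$temperature_c <- suppressWarnings(as.numeric(dat$temperature_c))
  if (anyDuplicated(dat$sample_id))
    stop("duplicate sample_id in metadata")
  bad <- is.na(dat$temperature_c) | !nzchar(dat$enzyme)
  if (any(bad))
    stop("missing enzyme/temperature for sample(s): ",
         paste(dat$sample_id[bad], collapse = ", "))
  dat$condition <- make_condition(dat$enzyme, dat$temperature_c)
  dat[, c(req, "condition")]
}

#' Check referential closure between the loaded inputs
#'
#' Every OTU in the count table must have a taxonomy entry (and a sequence,
#' when GC analysis is requested); every sample must have metadata. All
#' violations are collected and returned, not just the first.
#'
#' @param table OTU count matrix.
#' @param taxonomy taxonomy data.frame from [read_taxonomy()].
#' @param metadata optional metadata data.frame from [read_metadata()].
#' @param seqs optional named sequence vector from [read_fasta()].
#' @return character vector of violation messages (empty when closed).
#' @export
check_join_closure <- function(table, taxonomy, metadata = NULL, seqs = NULL) {
  probs <- character()
  miss_tax <- setdiff(colnames(table), taxonomy$otu_id)
  if (length(miss_tax))
    probs <- c(probs, paste0("OTU without taxonomy entry: ", miss_tax))
  if (!is.null(seqs)) {
    miss_seq <- setdiff(colnames(table), names(seqs))
    if (length(miss_seq))
      probs <- c(probs, paste0("OTU without representative sequence: ", miss_seq))
  }
  if (!is.null(metadata)) {
    miss_meta <- setdiff(rownames(table), metadata$sample_id)
    if (length(miss_meta))
      probs <- c(probs, paste0("sample without metadata: ", miss_meta))
  }
  probs
}

#' @rdname check_join_closure
#' @export
assert_join_closure <- function(table, taxonomy, metadata = NULL, seqs = NULL) {
  probs <- check_join_closure(table, taxonomy, metadata, seqs)
  if (length(probs))
    stop("input join failure:\n", paste(probs, collapse = "\n"))
  invisible(TRUE)
}

# Shared writer for schema-tagged TSV outputs.
write_tsv_tagged <- function(df, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(SCHEMA_TAG, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
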
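# GC content of representative sequences and the abundance-weighted class GC
# used as the regression covariate.

# Expected G+C contribution per IUPAC code: the fraction of the code's
# expansion that is G or C (e.g. B = {C,G,T} -> 2/3).
IUPAC_GC <- c(A = 0, C = 1, G = 1, T = 0, U = 0,
              W = 0, S = 1, M = 0.5, K = 0.5, R = 0.5, Y = 0.5,
              B = 2/3, D = 1/3, H = 1/3, V = 2/3, N = 0.5)

#' Expected GC fraction of a nucleotide sequence
#'
#' Computes the mean per-position G+C contribution under the IUPAC alphabet:
#' ambiguity codes contribute the fraction of their expansion that is G or C
#' (N = 0.5, S = 1, W = 0, ...), so ambiguous positions do not bias the
#' sequence length.
#'
#' @param seq character vector of sequences (case-insensitive).
#' @return numeric vector of GC fractions in `[0, 1]`.
#' @export
gc_fraction <- function(seq) {
  vapply(seq, function(s) {
    if (is.na(s) || !nzchar(s)) stop("empty sequence")
    chars <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
    vals <- IUPAC_GC[chars]
    if (anyNA(vals))
      stop("non-IUPAC nucleotide character(s): ",
           paste(unique(chars[is.na(vals)]), collapse = ", "))
    mean(vals)
  }, numeric(1L), USE.NAMES = !is.null(names(seq)))
}

#' Abundance-weighted mean GC per taxonomic class
#'
#' For each class, the weighted average of member-OTU GC fractions with the
#' supplied abundances as weights. A class whose members all have zero weight
#' falls back to the unweighted mean (with a warning); classes with no
#' sequenced members are excluded (with a message).
#'
#' @param taxonomy taxonomy data.frame.
#' @param seqs named sequence vector (see [read_fasta()]).
#' @param weights named non-negative per-OTU abundances (e.g.
#'   [otu_weights()]); OTUs missing from `weights` get weight 0.
#' @param weight_basis label recording which abundance set the weights came
#'   from (default `"global"`).
#' @return data.frame with columns `class_label`, `weighted_gc`, `n_otus`,
#'   `weight_basis`.
#' @export
class_weighted_gc <- function(taxonomy, seqs, weights,
                              weight_basis = "global") {
  if (any(weights < 0, na.rm = TRUE)) stop("weights must be non-negative")
  gc <- gc_fraction(seqs)
  out <- list()
  for (cls in sort(unique(taxonomy$class_label))) {
    members <- taxonomy$otu_id[taxonomy$class_label == cls]
    members <- intersect(members, names(seqs))
    if (!length(members)) {
      message("class '", cls, "' has no sequenced members; excluded from GC")
      next
    }
    w <- weights[members]
    w[is.na(w)] <- 0
    g <- gc[members]
    if (sum(w) == 0) {
      warning("class '", cls,
              "' has all-zero weights; using unweighted mean GC")
      wgc <- mean(g)
    } else {
      wgc <- sum(w * g) / sum(w)
    }
    out[[cls]] <- data.frame(class_label = cls, weighted_gc = wgc,
                             n_otus = length(members),
                             weight_basis = weight_basis,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Global per-OTU abundance weights
#'
#' Mean relative abundance of each OTU across all samples of a table: the
#' default weight basis for [class_weighted_gc()], giving a single GC
#' covariate shared by every condition pair.
#'
#' @param table OTU count matrix.
#' @return named numeric vector of mean relative abundances.
#' @export
otu_weights <- function(table) {
  colMeans(table / rowSums(table))
}

#' Reverse-complement a nucleotide sequence
#'
#' IUPAC-aware; used for strand-symmetry checks of GC content.
#'
#' @param seq character vector of sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", U = "A",
            W = "W", S = "S", M = "K", K = "M", R = "Y", Y = "R",
            B = "V", V = "B", D = "H", H = "D", N = "N")
  vapply(seq, function(s) {
    chars <- rev(strsplit(toupper(s), "", fixed = TRUE)[[1L]])
    paste(comp[chars], collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}
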
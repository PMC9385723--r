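#' Construct a Genome object
#'
#' A `genome` holds a single nucleotide sequence (uppercase, alphabet
#' `A`/`C`/`G`/`T`/`N`), its topology, and optionally gene features and a
#' quadripartite region map. All coordinates throughout the package are
#' 1-based inclusive (GenBank convention). On circular genomes an interval
#' with `start > end` wraps the origin, meaning `[start, L] U [1, end]`.
#'
#' @param id record identifier.
#' @param seq nucleotide string; lower case is folded to upper case.
#'   Ambiguity codes other than `N` are rejected.
#' @param circular logical topology flag.
#' @param features optional data.frame of gene features with columns
#'   `name`, `kind` (`CDS`, `tRNA`, `rRNA`, `other`), `strand` (`+`/`-`),
#'   `start`, `end`, `part` (interval index within a multi-interval gene).
#' @param regions optional named list of `c(start, end)` intervals for
#'   `LSC`, `IRa`, `SSC`, `IRb`.
#' @return an object of class `genome`.
#' @export
genome <- function(id, seq, circular = FALSE, features = NULL, regions = NULL) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("genome '", id, "': empty sequence")
  bad <- regmatches(seq, regexpr("[^ACGTN]", seq))
  if (length(bad) > 0L) {
    off <- regexpr("[^ACGTN]", seq)
    stop("genome '", id, "': illegal character '", bad,
         "' at offset ", as.integer(off))
  }
  if (!is.null(features)) features <- validate_features(features, nchar(seq))
  g <- structure(list(id = id, seq = seq, circular = isTRUE(circular),
                      features = features, regions = regions),
                 class = "genome")
  g
}

validate_features <- function(features, L) {
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  need <- c("name", "strand", "start", "end")
  miss <- setdiff(need, names(features))
  if (length(miss)) stop("features missing columns: ", paste(miss, collapse = ", "))
  if (is.null(features$kind)) features$kind <- "other"
  if (is.null(features$part)) features$part <- 1L
  stopifnot(all(features$strand %in% c("+", "-")))
  if (any(features$start < 1L | features$end < 1L |
          features$start > L | features$end > L))
    stop("feature coordinates outside [1, ", L, "]")
  features
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %s bp, %s%s%s\n", x$id,
              format(nchar(x$seq), big.mark = ","),
              if (x$circular) "circular" else "linear",
              if (!is.null(x$features))
                sprintf(", %d feature rows", nrow(x$features)) else "",
              if (!is.null(x$regions)) ", quadripartite regions set" else ""))
  invisible(x)
}

#' Genome length in base pairs
#' @param g a `genome`.
#' @return integer length.
#' @export
genome_length <- function(g) nchar(g$seq)

#' Reverse complement of a nucleotide string
#'
#' `N` maps to `N`. Input alphabet is `A`/`C`/`G`/`T`/`N` (either case).
#'
#' @param seq nucleotide string.
#' @return the reverse complement, upper case.
#' @export
revcomp <- function(seq) {
  if (nchar(seq) == 0L) return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

## substring with circular wrap: interval start > end means [start,L] U [1,end]
#' Extract a (possibly origin-wrapping) subsequence
#' @param g a `genome`.
#' @param start,end 1-based inclusive coordinates; `start > end` wraps the
#'   origin (only allowed on circular genomes).
#' @return nucleotide string.
#' @export
genome_subseq <- function(g, start, end) {
  L <- nchar(g$seq)
  stopifnot(start >= 1L, end >= 1L, start <= L, end <= L)
  if (start <= end) return(substr(g$seq, start, end))
  if (!g$circular) stop("wrapping interval on a linear genome")
  paste0(substr(g$seq, start, L), substr(g$seq, 1L, end))
}

#' GC content over non-N bases
#' @param g a `genome` (or plain nucleotide string).
#' @return fraction in `[0, 1]`.
#' @export
gc_content <- function(g) {
  comp <- base_composition(g)
  unname(comp["G"] + comp["C"])
}

#' Base composition over non-N bases
#' @param g a `genome` (or plain nucleotide string).
#' @return named numeric vector of fractions for `A`, `C`, `G`, `T`.
#' @export
base_composition <- function(g) {
  seq <- if (inherits(g, "genome")) g$seq else toupper(g)
  counts <- table(factor(strsplit(seq, "", fixed = TRUE)[[1]],
                         levels = c("A", "C", "G", "T", "N")))
  n <- sum(counts[c("A", "C", "G", "T")])
  if (n == 0L) stop("sequence contains no unambiguous bases")
  out <- as.numeric(counts[c("A", "C", "G", "T")]) / n
  names(out) <- c("A", "C", "G", "T")
  out
}

## circular sequence identity up to rotation, optionally reverse complement
seq_rotation_of <- function(a, b) {
  nchar(a) == nchar(b) && grepl(a, paste0(b, b), fixed = TRUE)
}

#' Are two circular sequences identical up to rotation / reverse complement?
#' @param a,b nucleotide strings interpreted as circles.
#' @param allow_revcomp also accept the reverse complement of `a`.
#' @return logical.
#' @export
circular_equal <- function(a, b, allow_revcomp = TRUE) {
  if (nchar(a) != nchar(b)) return(FALSE)
  seq_rotation_of(a, b) || (allow_revcomp && seq_rotation_of(revcomp(a), b))
}

#' Per-genome summary statistics
#' @param g a `genome`.
#' @return one-row data.frame: id, length_bp, gc_percent, and base
#'   percentages (all rounded to 2 decimals as reported).
#' @export
genome_stats <- function(g) {
  comp <- base_composition(g)
  data.frame(id = g$id,
             length_bp = genome_length(g),
             gc_percent = round(100 * (comp[["G"]] + comp[["C"]]), 2),
             a_percent = round(100 * comp[["A"]], 2),
             c_percent = round(100 * comp[["C"]], 2),
             g_percent = round(100 * comp[["G"]], 2),
             t_percent = round(100 * comp[["T"]], 2),
             stringsAsFactors = FALSE)
}

## uniform random nucleotide string; gc gives the G+C fraction
random_seq <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
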
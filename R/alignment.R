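# Alignment container: a character matrix, rows = terminals, columns = sites.

# Symbols recognised in an aligned DNA matrix. Everything outside UNAMBIGUOUS
# is treated as missing by every scoring function in the package.
GG_UNAMBIGUOUS <- c("A", "C", "G", "T")
GG_AMBIGUITY <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
GG_MISSING <- c("N", "?", "-")
GG_ALPHABET <- c(GG_UNAMBIGUOUS, GG_AMBIGUITY, GG_MISSING)

#' Construct an alignment from a character matrix
#'
#' An alignment is stored as an upper-case character matrix with one row per
#' terminal (row names are the terminal identifiers) and one column per
#' aligned site. Symbols are DNA bases `A`, `C`, `G`, `T`, the IUPAC
#' ambiguity codes, gap `-` and missing `N`/`?`. Any other symbol is
#' replaced by `?` with a warning. All scoring functions treat ambiguity
#' codes, gaps and missing codes alike: as missing data.
#'
#' @param x character matrix (or object coercible to one) with unique,
#'   non-empty row names.
#' @return an object of class `gg_alignment` (a character matrix).
#' @export
as_alignment <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop("alignment must have at least one terminal and one column")
  }
  ids <- trimws(rownames(x))
  if (is.null(rownames(x)) || any(!nzchar(ids))) {
    stop("alignment rows must be named by terminal identifiers")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate terminal identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  rownames(x) <- ids
  storage.mode(x) <- "character"
  x[] <- toupper(x)
  bad <- !(x %in% GG_ALPHABET)
  if (any(bad)) {
    warning(sum(bad), " unrecognised symbol(s) (",
            paste(unique(x[bad]), collapse = ", "),
            ") replaced by '?'")
    x[bad] <- "?"
  }
  class(x) <- c("gg_alignment", class(x))
  x
}

#' Read an aligned FASTA file
#'
#' All records must have identical length (the matrix is assumed to be
#' pre-aligned); symbols are upper-cased and unknown symbols are mapped to
#' `?` with a warning.
#'
#' @param path path to a FASTA file.
#' @return a [as_alignment()] matrix.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  seqs <- seqinr::read.fasta(path, seqtype = "DNA",
                             forceDNAtolower = FALSE,
                             set.attributes = FALSE)
  if (length(seqs) == 0L) stop("no FASTA records in ", path)
  lens <- lengths(seqs)
  if (length(unique(lens)) > 1L) {
    ref <- max(lens)
    off <- names(seqs)[lens != ref]
    stop("records not aligned to equal length; offending record(s): ",
         paste(off, collapse = ", "))
  }
  m <- do.call(rbind, seqs)
  rownames(m) <- names(seqs)
  as_alignment(m)
}

#' Write an alignment to FASTA
#'
#' @param aln a `gg_alignment`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  aln <- as_alignment(aln)
  seqinr::write.fasta(
    sequences = lapply(seq_len(nrow(aln)), function(i) aln[i, ]),
    names = rownames(aln), file.out = path, nbchar = 80
  )
  invisible(path)
}

#' @export
print.gg_alignment <- function(x, ...) {
  cat("Alignment:", nrow(x), "terminals x", ncol(x), "columns\n")
  invisible(x)
}

# TRUE for cells carrying an unambiguous base.
is_unambiguous <- function(x) x %in% GG_UNAMBIGUOUS
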
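# Taxonomy table: data frame keyed by terminal id with one column per rank.
# Concordance groups (named taxa expected to be clades) and their binary
# membership characters are derived from it.

GG_RANKS <- c("genus", "subfamily", "family", "superfamily")

#' Read a taxonomy table
#'
#' Expects a TSV with header `terminal genus subfamily family superfamily`
#' (additional rank columns are allowed). Identifiers are matched to
#' alignments and trees by exact string comparison after whitespace
#' trimming; missing group assignments may be left empty or `NA`.
#'
#' @param path path to a tab-separated file.
#' @return a data frame with column `terminal` plus one column per rank.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  tax <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           na.strings = c("", "NA"))
  validate_taxonomy(tax)
}

validate_taxonomy <- function(tax) {
  tax <- as.data.frame(tax, stringsAsFactors = FALSE)
  if (!"terminal" %in% names(tax)) {
    stop("taxonomy table must have a 'terminal' column")
  }
  tax$terminal <- trimws(tax$terminal)
  if (anyDuplicated(tax$terminal)) {
    stop("duplicate terminals in taxonomy: ",
         paste(unique(tax$terminal[duplicated(tax$terminal)]), collapse = ", "))
  }
  if (ncol(tax) < 2L) stop("taxonomy table has no rank columns")
  tax
}

#' Write a taxonomy table to TSV
#' @param tax taxonomy data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.table(tax, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

rank_column <- function(tax, rank) {
  if (!rank %in% names(tax)) {
    stop("rank '", rank, "' not found in taxonomy table (available: ",
         paste(setdiff(names(tax), "terminal"), collapse = ", "), ")")
  }
  stats::setNames(tax[[rank]], tax$terminal)
}

#' List concordance groups at a rank
#'
#' A concordance group is a named taxon at the given rank together with its
#' member terminals; groups are candidates for monophyly on a tree.
#' Terminals with a missing value at the rank are excluded with a warning.
#'
#' @param tax taxonomy data frame.
#' @param rank rank name (a column of `tax`).
#' @param terminals terminal ids under analysis (default: all in `tax`).
#' @param min_size keep only groups with at least this many members
#'   (the per-taxon analyses use 3, i.e. taxa represented by three or more
#'   species; membership characters use 1).
#' @return named list of character vectors of member ids.
#' @export
concordance_groups <- function(tax, rank, terminals = tax$terminal,
                               min_size = 1L) {
  terminals <- trimws(terminals)
  absent <- setdiff(terminals, tax$terminal)
  if (length(absent)) {
    stop("terminals absent from taxonomy: ", paste(absent, collapse = ", "))
  }
  grp <- rank_column(tax, rank)[terminals]
  if (all(is.na(grp))) stop("all values missing at rank '", rank, "'")
  if (anyNA(grp)) {
    warning(sum(is.na(grp)), " terminal(s) with missing '", rank,
            "' excluded")
    terminals <- terminals[!is.na(grp)]
    grp <- grp[!is.na(grp)]
  }
  groups <- split(terminals, grp)
  groups <- groups[lengths(groups) >= min_size]
  groups[order(names(groups))]
}

#' Build a binary membership matrix for concordance groups
#'
#' One binary character per group at the rank: state 1 for members, 0 for
#' non-members. Scoring these characters on a cladogram yields the
#' taxonomic-congruence indices.
#'
#' @inheritParams concordance_groups
#' @return integer matrix (terminals x groups) of 0/1 states with class
#'   `gg_membership`; attribute `rank` records the rank.
#' @export
build_membership_matrix <- function(tax, rank, terminals = tax$terminal,
                                    min_size = 1L) {
  groups <- concordance_groups(tax, rank, terminals, min_size = min_size)
  if (length(groups) == 0L) {
    warning("no group at rank '", rank, "' with >= ", min_size, " members")
  }
  terminals <- trimws(terminals)
  m <- vapply(groups, function(members) as.integer(terminals %in% members),
              integer(length(terminals)))
  m <- matrix(m, nrow = length(terminals),
              dimnames = list(terminals, names(groups)))
  structure(m, rank = rank, class = c("gg_membership", class(m)))
}
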
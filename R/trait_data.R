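#' Read and validate a rooted phylogeny from Newick
#'
#' Reads a Newick string (or a file containing one) into an [ape::read.tree]
#' `phylo` object and enforces the invariants the downstream likelihood
#' machinery relies on: unique tip labels, branch lengths present and
#' non-negative, a single root.
#'
#' @param newick Either a literal Newick string (recognised by the presence
#'   of a parenthesis) or the path to a file containing one.
#' @return A `phylo` object.
#' @export
read_phylogeny <- function(newick) {
  if (length(newick) != 1L || !is.character(newick))
    stop("`newick` must be a single string or file path")
  tree <- if (grepl("(", newick, fixed = TRUE))
    ape::read.tree(text = newick)
  else
    ape::read.tree(file = newick)
  if (is.null(tree))
    stop("malformed Newick input")
  validate_phylogeny(tree)
  tree
}

validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo"))
    stop("not a `phylo` object")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  neg <- which(tree$edge.length < 0)
  if (length(neg))
    stop("negative branch length at edge ", neg[1],
         " (", tree$edge.length[neg[1]], ")")
  ntip <- length(tree$tip.label)
  # the root is the one node that never appears as a child
  children <- tree$edge[, 2]
  parents <- unique(tree$edge[, 1])
  roots <- setdiff(parents, children)
  if (length(roots) != 1L)
    stop("tree must have exactly one root")
  if (nrow(tree$edge) < ntip)
    stop("tree edges do not connect all tips")
  invisible(tree)
}

#' Read a species-by-trait table of binary traits
#'
#' Reads a delimited table (CSV or TSV, auto-detected) with a species column
#' and named 0/1 trait columns. Rows with a missing value in any requested
#' trait are dropped (complete-case rule) and reported via the `"dropped"`
#' attribute. Any non-missing value other than 0 or 1 is an error: trait
#' coding is strict, 1 = presence, 0 = absence.
#'
#' @param table_text Path to a file, or literal table text (recognised by an
#'   embedded newline).
#' @param trait_names Character vector of trait columns to extract.
#' @param species_col Name of the species column (default `"species"`).
#' @param normalize_names Replace spaces with underscores and trim
#'   whitespace in species names (default TRUE), so names match Newick tip
#'   labels.
#' @return Integer matrix with species rownames and one column per trait;
#'   attribute `"dropped"` lists species removed by the complete-case rule.
#' @export
read_traits <- function(table_text, trait_names, species_col = "species",
                        normalize_names = TRUE) {
  con_text <- grepl("\n", table_text, fixed = TRUE)
  first_line <- if (con_text) strsplit(table_text, "\n")[[1]][1]
                else readLines(table_text, n = 1L)
  sep <- if (grepl("\t", first_line, fixed = TRUE)) "\t" else ","
  src <- if (con_text) textConnection(table_text) else table_text
  tab <- read.table(src, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    colClasses = "character", strip.white = TRUE)
  if (!species_col %in% names(tab))
    stop("species column '", species_col, "' not found")
  missing_cols <- setdiff(trait_names, names(tab))
  if (length(missing_cols))
    stop("trait column(s) absent: ", paste(missing_cols, collapse = ", "))

  species <- trimws(tab[[species_col]])
  if (normalize_names) species <- gsub("[ ]+", "_", species)

  vals <- as.matrix(tab[, trait_names, drop = FALSE])
  vals[vals == ""] <- NA_character_
  bad <- !is.na(vals) & !(vals %in% c("0", "1"))
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, ]
    stop("non-binary trait value '", vals[bad][1], "' for species '",
         species[i[1]], "' in column '", trait_names[i[2]],
         "'; traits must be coded 0/1")
  }
  keep <- rowSums(is.na(vals)) == 0
  dropped <- species[!keep]
  out <- matrix(as.integer(vals[keep, , drop = FALSE]),
                ncol = length(trait_names),
                dimnames = list(species[keep], trait_names))
  if (nrow(out) == 0L)
    stop("no complete-case rows survive")
  if (anyDuplicated(rownames(out)))
    stop("duplicate species in trait table")
  attr(out, "dropped") <- dropped
  out
}

#' Align a phylogeny and a binary trait matrix
#'
#' Prunes the tree to the species shared with the trait table (degree-2
#' nodes collapsed, branch lengths summed, so patristic distances are
#' preserved), restricts and reorders the trait rows to tip order, and
#' reports how many species were dropped on each side.
#'
#' @param tree A `phylo` object.
#' @param traits Trait matrix from [read_traits()].
#' @return List with elements `tree`, `traits`, `dropped_tips` and
#'   `dropped_rows`.
#' @export
align_tree_traits <- function(tree, traits) {
  validate_phylogeny(tree)
  common <- intersect(tree$tip.label, rownames(traits))
  if (length(common) == 0L)
    stop("no species shared between tree and trait table")
  dropped_tips <- setdiff(tree$tip.label, common)
  dropped_rows <- setdiff(rownames(traits), common)
  pruned <- if (length(dropped_tips)) ape::keep.tip(tree, common) else tree
  list(tree = pruned,
       traits = traits[pruned$tip.label, , drop = FALSE],
       dropped_tips = dropped_tips,
       dropped_rows = dropped_rows)
}

#' Rescale branch lengths to a target mean
#'
#' Multiplies every branch by the single constant that makes the mean over
#' all branches (internal and terminal) equal `target_mean`. The
#' convention of scaling to a mean of 0.1 before the discrete analyses helps
#' the sampler explore small transition rates.
#'
#' @param tree A `phylo` object with at least one positive branch length.
#' @param target_mean Positive target mean branch length (default 0.1).
#' @return The rescaled tree; attribute `"scale_factor"` records the
#'   constant applied.
#' @export
scale_branch_lengths <- function(tree, target_mean = 0.1) {
  validate_phylogeny(tree)
  stopifnot(target_mean > 0)
  m <- mean(tree$edge.length)
  if (m <= 0)
    stop("all branch lengths are zero; cannot scale")
  cst <- target_mean / m
  tree$edge.length <- tree$edge.length * cst
  attr(tree, "scale_factor") <- cst
  tree
}
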
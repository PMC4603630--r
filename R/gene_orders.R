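## Extant gene orders -> extant adjacencies. An adjacency is an unordered
## pair of consecutive genes on one scaffold of one extant species;
## orientation is ignored, so the pair is canonicalized lexicographically.

#' Derive extant adjacencies from gene orders
#'
#' Reads a gene-order table (TSV with columns \code{species}, \code{scaffold},
#' \code{position}, \code{gene_id}; integer positions, gaps allowed) and
#' returns one adjacency per pair of consecutive genes within each
#' (species, scaffold). No adjacency spans two scaffolds.
#'
#' @param x Path to a TSV file, or a data.frame with the four columns.
#' @return A data.frame of class \code{adjacency_set} with columns
#'   \code{species}, \code{gene1}, \code{gene2} (\code{gene1 < gene2}).
#' @examples
#' go <- data.frame(species = "A", scaffold = "s1", position = 1:3,
#'                  gene_id = c("a1", "a2", "a3"))
#' load_gene_orders(go)
#' @export
load_gene_orders <- function(x) {
  if (is.character(x)) {
    x <- utils::read.delim(x, stringsAsFactors = FALSE,
                           colClasses = c(species = "character",
                                          scaffold = "character",
                                          gene_id = "character"))
  }
  need <- c("species", "scaffold", "position", "gene_id")
  if (!all(need %in% names(x)))
    stop("gene-order table needs columns: ", paste(need, collapse = ", "))
  key <- paste(x$species, x$scaffold, x$position, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (species, scaffold, position) in gene orders")
  gkey <- paste(x$species, x$gene_id, sep = "\r")
  if (anyDuplicated(gkey))
    stop("duplicate gene id within a species: ",
         x$gene_id[duplicated(gkey)][1])
  x <- x[order(x$species, x$scaffold, x$position), , drop = FALSE]
  grp <- paste(x$species, x$scaffold, sep = "\r")
  sp <- character(0); g1 <- character(0); g2 <- character(0)
  for (g in unique(grp)) {
    rows <- which(grp == g)
    if (length(rows) < 2L) next
    a <- x$gene_id[rows][-length(rows)]
    b <- x$gene_id[rows][-1]
    sp <- c(sp, x$species[rows][-1])
    g1 <- c(g1, pmin(a, b))
    g2 <- c(g2, pmax(a, b))
  }
  if (any(g1 == g2)) stop("self-adjacency (gene adjacent to itself)")
  out <- data.frame(species = sp, gene1 = g1, gene2 = g2,
                    stringsAsFactors = FALSE)
  class(out) <- c("adjacency_set", "data.frame")
  out
}

.adj_key <- function(adj) paste(adj$species, adj$gene1, adj$gene2, sep = "\r")
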
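#' Read and validate a phylogeny
#'
#' Thin wrapper around ape's Newick reader that enforces the contracts the
#' downstream statistics rely on: a single rooted tree, unique tip labels,
#' and non-negative branch lengths on every edge.
#'
#' @param source Path to a Newick file, a Newick string, or a `phylo` object.
#' @return An ape `phylo` object.
#' @export
#' @examples
#' tr <- read_phylogeny("((A:1,B:1):1,C:2);")
#' tr$Nnode
read_phylogeny <- function(source) {
  tr <- if (inherits(source, "phylo")) {
    source
  } else if (length(source) == 1 && grepl(";", source, fixed = TRUE)) {
    ape::read.tree(text = source)
  } else {
    ape::read.tree(source)
  }
  if (is.null(tr)) stop("malformed Newick input", call. = FALSE)
  if (inherits(tr, "multiPhylo")) stop("expected a single tree", call. = FALSE)
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels", call. = FALSE)
  if (is.null(tr$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (any(tr$edge.length < 0)) stop("negative branch length", call. = FALSE)
  tr
}

#' Write a phylogeny to Newick
#'
#' @param tree A `phylo` object.
#' @param path Output file; if missing, the Newick string is returned.
#' @return The Newick string, invisibly when written to file.
#' @export
write_phylogeny <- function(tree, path) {
  if (missing(path)) ape::write.tree(tree)
  else invisible(ape::write.tree(tree, file = path))
}

#' Phylogenetic variance-covariance matrix
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips i and j; the
#' diagonal holds root-to-tip depths. This is the trait covariance structure
#' implied by Brownian motion on the tree (up to the rate).
#'
#' @param tree A `phylo` object with branch lengths.
#' @return Symmetric tips-by-tips matrix with tip labels as dimnames.
#' @export
vcv_matrix <- function(tree) {
  tree <- read_phylogeny(tree)
  ape::vcv.phylo(tree)
}

#' Patristic distance matrix
#'
#' `D[i, j]` is the sum of branch lengths along the path between tips i and
#' j; equivalently `depth_i + depth_j - 2 C[i, j]`.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return Symmetric tips-by-tips matrix, zero diagonal.
#' @export
patristic_matrix <- function(tree) {
  tree <- read_phylogeny(tree)
  C <- ape::vcv.phylo(tree)
  depth <- diag(C)
  D <- outer(depth, depth, "+") - 2 * C
  D[D < 0] <- 0  # guard against roundoff
  D
}

#' Abouheif phylogenetic proximity matrix
#'
#' Topology-only proximity: `A[i, j]` is the reciprocal of the product, over
#' the internal nodes on the path between tips i and j, of the number of
#' direct descendants of each node. Diagonal is zero. Branch lengths are
#' ignored, so the matrix is invariant to any rescaling of the tree.
#'
#' @param tree A `phylo` object.
#' @return Symmetric tips-by-tips matrix, zero diagonal.
#' @export
abouheif_proximity <- function(tree) {
  tree <- read_phylogeny(tree)
  n <- length(tree$tip.label)
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  nchild <- tabulate(tree$edge[, 1], nbins = max(tree$edge))
  root <- n + 1L
  # ancestors of each tip, tipward to root
  anc <- lapply(seq_len(n), function(i) {
    a <- integer(0); v <- i
    while (v != root) { v <- parent[v]; a <- c(a, v) }
    a
  })
  A <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      mrca <- anc[[i]][match(TRUE, anc[[i]] %in% anc[[j]])]
      path_nodes <- c(
        anc[[i]][seq_len(match(mrca, anc[[i]]))],
        anc[[j]][seq_len(match(mrca, anc[[j]]) - 1)]
      )
      A[i, j] <- A[j, i] <- 1 / prod(nchild[path_nodes])
    }
  }
  A
}

#' Resolve multichotomies randomly
#'
#' Polytomies are expanded into a random binary resolution with zero-length
#' inserted branches (so all patristic distances are preserved), seeded for
#' reproducibility.
#'
#' @param tree A `phylo` object.
#' @param seed Integer seed.
#' @return A strictly binary `phylo` object.
#' @export
resolve_multichotomies <- function(tree, seed = 1L) {
  tree <- read_phylogeny(tree)
  if (ape::is.binary(tree)) return(tree)
  with_seed(seed, ape::multi2di(tree, random = TRUE))
}

#' Rename tips by an explicit substitution mapping
#'
#' Used when a required species is absent from a reference tree and a close
#' relative stands in for it: the stand-in tip is relabelled to the target
#' species; topology and branch lengths are untouched.
#'
#' @param tree A `phylo` object.
#' @param mapping Named character vector, `old_label = "new_label"`.
#' @return The relabelled tree.
#' @export
substitute_taxa <- function(tree, mapping) {
  tree <- read_phylogeny(tree)
  if (length(mapping) == 0) return(tree)
  if (is.null(names(mapping))) stop("mapping must be named (old -> new)", call. = FALSE)
  miss <- setdiff(names(mapping), tree$tip.label)
  if (length(miss)) stop("not a tip: ", paste(miss, collapse = ", "), call. = FALSE)
  clash <- intersect(unname(mapping), setdiff(tree$tip.label, names(mapping)))
  if (length(clash)) stop("label already present: ", paste(clash, collapse = ", "),
                          call. = FALSE)
  idx <- match(names(mapping), tree$tip.label)
  tree$tip.label[idx] <- unname(mapping)
  if (anyDuplicated(tree$tip.label)) stop("mapping creates duplicate labels", call. = FALSE)
  tree
}

#' Ultrametric fallback tree from a taxonomy
#'
#' When no calibrated phylogeny is available, builds a three-level ultrametric
#' tree: species within a genus diverge at `depths["genus"]`, genera within a
#' family at `depths["family"]`, families at `depths["root"]` (time before
#' present). Single-genus families and single-species genera collapse (no
#' unary nodes). The result is full of multichotomies by construction; pass
#' it through [resolve_multichotomies()] before likelihood-based analyses.
#'
#' @param taxonomy Taxonomy from [load_taxonomy()].
#' @param depths Named numeric: `root` > `family` > `genus` > 0.
#' @return An ultrametric `phylo` object; tip labels are species names with
#'   spaces replaced by underscores (see [species_to_tip()]).
#' @export
taxonomy_tree <- function(taxonomy, depths = c(root = 3, family = 2, genus = 1)) {
  stopifnot(depths["root"] > depths["family"], depths["family"] > depths["genus"],
            depths["genus"] > 0)
  clade <- function(labels, stems) {
    if (length(labels) == 1) return(sprintf("%s:%g", labels, stems))
    sprintf("(%s):%g", paste(labels, collapse = ","), stems)
  }
  fam_strings <- vapply(split(taxonomy, taxonomy$family), function(fam) {
    gen_strings <- vapply(split(fam, fam$genus), function(gen) {
      tips <- sprintf("%s:%g", species_to_tip(gen$species), depths["genus"])
      clade_len <- depths["family"] - depths["genus"]
      if (nrow(gen) == 1) {
        sprintf("%s:%g", species_to_tip(gen$species), depths["family"])
      } else {
        sprintf("(%s):%g", paste(tips, collapse = ","), clade_len)
      }
    }, character(1))
    clade_len <- depths["root"] - depths["family"]
    if (length(gen_strings) == 1) {
      # collapse: genus node carries the family's full stem
      gen <- split(fam, fam$genus)[[1]]
      if (nrow(gen) == 1) {
        sprintf("%s:%g", species_to_tip(gen$species), depths["root"])
      } else {
        tips <- sprintf("%s:%g", species_to_tip(gen$species), depths["genus"])
        sprintf("(%s):%g", paste(tips, collapse = ","),
                depths["root"] - depths["genus"])
      }
    } else {
      sprintf("(%s):%g", paste(gen_strings, collapse = ","), clade_len)
    }
  }, character(1))
  txt <- if (length(fam_strings) == 1) {
    sub(":[0-9.eE+-]+$", ";", fam_strings)
  } else {
    sprintf("(%s);", paste(fam_strings, collapse = ","))
  }
  read_phylogeny(txt)
}

#' Species name to tree tip label
#'
#' Newick tip labels use underscores where species names have spaces.
#' @param x Character vector of species names.
#' @return Tip labels.
#' @export
species_to_tip <- function(x) gsub(" ", "_", x, fixed = TRUE)

#' @rdname species_to_tip
#' @export
tip_to_species <- function(x) gsub("_", " ", x, fixed = TRUE)

#' Inverse-distance spatial weights from a tree
#'
#' Off-diagonal weights are `1/D[i, j]` (patristic), then row-normalized.
#' Zero patristic distances between distinct tips (possible after zero-length
#' polytomy resolution) are mapped to the largest finite proximity with a
#' warning.
#'
#' @param tree A `phylo` object.
#' @return Row-normalized weight matrix, zero diagonal.
#' @export
inverse_distance_weights <- function(tree) {
  D <- patristic_matrix(tree)
  off <- D[upper.tri(D)]
  if (any(off == 0)) {
    warning("zero patristic distance between distinct tips; using maximum finite proximity")
    minpos <- min(off[off > 0])
    D[D == 0] <- minpos
  }
  W <- 1 / D
  diag(W) <- 0
  row_normalize(W)
}

#' Row-normalize a weight matrix
#'
#' @param W Non-negative matrix with zero diagonal.
#' @return Matrix whose rows sum to 1 (all-zero rows are left as zero).
#' @export
row_normalize <- function(W) {
  rs <- rowSums(W)
  rs[rs == 0] <- 1
  W / rs
}

# run `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
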
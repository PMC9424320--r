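## Circular (Morgan-style) count fingerprints of molecules and reactions.
## Molecules are parsed from SMILES with ChemmineR/Open Babel; atom
## environments of increasing radius are hashed and folded into a fixed-width
## count vector. A reaction fingerprint is the elementwise sum of its
## substrate and product fingerprints.

FP_BITS <- 4096L

fp_cache <- new.env(parent = emptyenv())

## heavy-atom graph of a molecule: element symbols + bond table
molecule_graph <- function(smiles) {
  ## bond-less molecules (a bare atom, e.g. methane "C") round-trip badly
  ## through the SDF converter; their graph is trivial anyway
  if (grepl("^\\[?([A-Z][a-z]?)[0-9+-]*\\]?$", smiles)) {
    elem <- sub("^\\[?([A-Z][a-z]?).*$", "\\1", smiles)
    return(list(elements = elem,
                bonds = data.frame(from = integer(), to = integer(),
                                   order = integer())))
  }
  sdf <- ChemmineR::smiles2sdf(smiles)[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  if (!all(grepl("^[A-Z][a-z]?$", elements))) {
    stop(sprintf("could not parse SMILES '%s'", smiles))
  }
  n <- length(elements)
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) {
    data.frame(from = integer(), to = integer(), order = integer())
  } else {
    b <- data.frame(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
                    order = as.integer(bb[, 3]))
    b[b$from >= 1 & b$from <= n & b$to >= 1 & b$to <= n & b$order >= 1, ,
      drop = FALSE]
  }
  list(elements = elements, bonds = bonds)
}

#' Morgan-style circular count fingerprint of a molecule
#'
#' Atom environments of radius 0 up to `radius` are iteratively hashed from
#' (element, degree, total bond order) seeds and the sorted neighbor
#' environments, then folded into `nbits` counting bins. The construction is
#' invariant to atom ordering in the input SMILES: two SMILES of the same
#' molecule give identical vectors.
#'
#' @param smiles a single SMILES string.
#' @param nbits fold width (default 4096).
#' @param radius maximum environment radius (default 2).
#' @return integer count vector of length `nbits`.
#' @export
morgan_fingerprint <- function(smiles, nbits = FP_BITS, radius = 2L) {
  key <- sprintf("%s|%d|%d", smiles, nbits, radius)
  hit <- fp_cache[[key]]
  if (!is.null(hit)) return(hit)

  g <- molecule_graph(smiles)
  n <- length(g$elements)
  deg <- integer(n)
  bondsum <- integer(n)
  nbrs <- vector("list", n)
  for (i in seq_len(nrow(g$bonds))) {
    a <- g$bonds$from[i]; b <- g$bonds$to[i]; o <- g$bonds$order[i]
    deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
    bondsum[a] <- bondsum[a] + o; bondsum[b] <- bondsum[b] + o
    nbrs[[a]] <- rbind(nbrs[[a]], c(b, o))
    nbrs[[b]] <- rbind(nbrs[[b]], c(a, o))
  }
  inv <- vapply(seq_len(n), function(i) {
    fnv1a32(paste(g$elements[i], deg[i], bondsum[i], sep = "|"))
  }, numeric(1))

  fp <- integer(nbits)
  fold <- function(vals) {
    idx <- (vals %% nbits) + 1
    for (ix in idx) fp[ix] <<- fp[ix] + 1L
  }
  fold(inv)
  for (r in seq_len(radius)) {
    inv_new <- vapply(seq_len(n), function(i) {
      nb <- nbrs[[i]]
      env <- if (is.null(nb)) "" else {
        paste(sort(sprintf("%d:%.0f", nb[, 2], inv[nb[, 1]])), collapse = ",")
      }
      fnv1a32(sprintf("%.0f|%s", inv[i], env))
    }, numeric(1))
    inv <- inv_new
    fold(inv)
  }
  fp_cache[[key]] <- fp
  fp
}

species_structure <- function(sp) {
  if (!is.null(sp$smiles)) return(sp$smiles)
  if (!is.null(sp$inchi)) {
    smi <- tryCatch(
      trimws(ChemmineOB::convertFormat("INCHI", "SMI", sp$inchi)),
      error = function(e) NULL)
    smi <- sub("\t.*$", "", smi %||% "")
    if (nzchar(smi %||% "")) return(smi)
  }
  NULL
}

#' Reaction fingerprint
#'
#' Elementwise sum of the circular fingerprints of all substrates plus those
#' of all products (one contribution per participating species; additive by
#' definition).
#'
#' @param r an `rp_reaction` (or any list with `reactants`/`products` named
#'   numeric vectors).
#' @param species named list of `rp_species` providing SMILES (or InChI) for
#'   every participant.
#' @param nbits,radius as in [morgan_fingerprint()].
#' @return integer count vector of length `nbits`.
#' @export
reaction_fingerprint <- function(r, species, nbits = FP_BITS, radius = 2L) {
  fp <- integer(nbits)
  for (sid in c(names(r$reactants), names(r$products))) {
    sp <- species[[sid]]
    structure_str <- if (is.null(sp)) NULL else species_structure(sp)
    if (is.null(structure_str)) {
      stop(sprintf("species '%s' has no usable structure (SMILES/InChI) for fingerprinting", sid))
    }
    fp <- fp + morgan_fingerprint(structure_str, nbits, radius)
  }
  fp
}
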
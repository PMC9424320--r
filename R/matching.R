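## Similarity between a predicted pathway and a literature reference pathway.
## Steps are compared on main (non-cofactor) substrate/product identity —
## first InChIKey block when available, else species id — and on EC number
## agreement down to three levels; an order-preserving assignment aligns
## predicted reactions to reference steps.

## currency metabolites excluded from "main" substrates/products by default
DEFAULT_COFACTORS <- c(
  "MNXM1", "MNXM2", "MNXM3", "MNXM4", "MNXM5", "MNXM6", "MNXM8", "MNXM9",
  "MNXM10", "MNXM13", "MNXM15",
  "WATER", "PROTON", "ATP", "ADP", "AMP", "NAD", "NADH", "NADP", "NADPH",
  "CO2", "O2", "PI", "PPI", "COA", "H2O2"
)

#' Reference (literature) pathway
#'
#' @param target_id target species identifier (or InChIKey).
#' @param steps non-empty list of steps, each a list with `ec` (character
#'   vector of EC numbers), `substrates` and `products` (character vectors of
#'   species identities: InChIKeys or ids).
#' @return an object of class `rp_reference`.
#' @export
reference_pathway <- function(target_id, steps) {
  if (!length(steps)) stop("reference pathway needs at least one step")
  structure(list(target_id = target_id, steps = steps), class = "rp_reference")
}

#' Read reference pathways from CSV
#'
#' Columns: `pathway_id`, `target_id`, `step` (integer order), `ec`,
#' `substrates`, `products`; multiple values within a cell are
#' semicolon-separated.
#'
#' @param path CSV file path or data frame.
#' @return named list of [reference_pathway()] objects.
#' @export
read_reference_pathways <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  split_cell <- function(x) {
    out <- strsplit(as.character(x), ";", fixed = TRUE)[[1]]
    trimws(out[nzchar(trimws(out))])
  }
  out <- list()
  for (pid in unique(df$pathway_id)) {
    rows <- df[df$pathway_id == pid, , drop = FALSE]
    rows <- rows[order(rows$step), , drop = FALSE]
    steps <- lapply(seq_len(nrow(rows)), function(i) {
      list(ec = split_cell(rows$ec[i]),
           substrates = split_cell(rows$substrates[i]),
           products = split_cell(rows$products[i]))
    })
    out[[pid]] <- reference_pathway(rows$target_id[1], steps)
  }
  out
}

## species identity for matching: first InChIKey block when present, else id
match_identity <- function(sid, species) {
  sp <- species[[sid]]
  if (!is.null(sp) && !is.null(sp$inchikey)) return(inchikey_block1(sp$inchikey))
  if (is_inchikey(sid)) return(inchikey_block1(sid))
  sid
}

#' Convert a pathway to reference form
#'
#' Builds one reference step per reaction, using main (non-cofactor)
#' substrates and products identified by first InChIKey block where
#' structures are known.
#'
#' @param p an `rp_pathway`.
#' @param cofactors ids treated as currency metabolites and dropped from the
#'   main species sets.
#' @return an `rp_reference`.
#' @export
as_reference <- function(p, cofactors = DEFAULT_COFACTORS) {
  steps <- lapply(p$reactions, function(r) {
    subs <- setdiff(names(r$reactants), cofactors)
    prods <- setdiff(names(r$products), cofactors)
    list(ec = r$ec_numbers,
         substrates = vapply(subs, match_identity, character(1), species = p$species),
         products = vapply(prods, match_identity, character(1), species = p$species))
  })
  reference_pathway(match_identity(p$target_id, p$species), unname(steps))
}

ec_agreement <- function(ec_a, ec_b) {
  if (!length(ec_a) || !length(ec_b)) return(NA_real_)
  best <- 0
  for (a in ec_a) {
    pa <- strsplit(a, ".", fixed = TRUE)[[1]]
    for (b in ec_b) {
      pb <- strsplit(b, ".", fixed = TRUE)[[1]]
      lvl <- 0
      for (i in seq_len(min(3, length(pa), length(pb)))) {
        if (identical(pa[i], pb[i])) lvl <- lvl + 1 else break
      }
      best <- max(best, lvl / 3)
    }
  }
  best
}

step_similarity <- function(step_a, step_b) {
  set_a <- unique(c(step_a$substrates, step_a$products))
  set_b <- unique(c(step_b$substrates, step_b$products))
  jac <- if (!length(set_a) && !length(set_b)) 1 else {
    length(intersect(set_a, set_b)) / length(union(set_a, set_b))
  }
  ec <- ec_agreement(step_a$ec, step_b$ec)
  ## weight renormalization: without EC evidence on both sides, chemistry
  ## carries the whole similarity
  if (is.na(ec)) jac else 0.5 * jac + 0.5 * ec
}

#' Match a predicted pathway against a reference pathway
#'
#' Per-step similarity combines main-substrate/product identity (Jaccard
#' index over first InChIKey blocks) with EC agreement matched to three
#' levels, equally weighted (chemistry alone when either side lacks EC
#' numbers). Predicted reactions are aligned to reference steps by dynamic
#' programming over order-preserving injective assignments maximizing total
#' similarity; the pathway score divides that total by the larger step
#' count, so unmatched steps on either side are penalized.
#'
#' @param p an `rp_pathway`.
#' @param ref an `rp_reference` (non-empty).
#' @param cofactors currency metabolites excluded from main species sets.
#' @return list of class `rp_match` with `score` in \[0, 1\] and `step_map`
#'   (named integer vector: predicted reaction id to reference step index).
#' @export
match_score <- function(p, ref, cofactors = DEFAULT_COFACTORS) {
  if (!inherits(ref, "rp_reference") || !length(ref$steps)) {
    stop("reference pathway is empty")
  }
  pred <- as_reference(p, cofactors)
  n <- length(pred$steps); m <- length(ref$steps)
  sim <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    sim[i, j] <- step_similarity(pred$steps[[i]], ref$steps[[j]])
  }
  ## order-preserving alignment (longest-common-subsequence style DP)
  M <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    M[i + 1, j + 1] <- max(M[i, j + 1], M[i + 1, j], M[i, j] + sim[i, j])
  }
  ## traceback for the step map
  step_map <- integer(0)
  i <- n; j <- m
  while (i > 0 && j > 0) {
    if (abs(M[i + 1, j + 1] - (M[i, j] + sim[i, j])) < 1e-12 && sim[i, j] > 0) {
      step_map[names(p$reactions)[i]] <- j
      i <- i - 1; j <- j - 1
    } else if (M[i, j + 1] >= M[i + 1, j]) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  structure(list(score = M[n + 1, m + 1] / max(n, m),
                 step_map = step_map[order(match(names(step_map), names(p$reactions)))]),
            class = "rp_match")
}

#' Label pathways as literature pathways
#'
#' A match counts as a literature pathway when its score is strictly above
#' 0.5; a score of exactly 0.5 does not qualify.
#'
#' @param results list of `rp_match` objects (or numeric scores).
#' @param threshold the cut, default 0.5.
#' @return logical vector.
#' @export
label_literature <- function(results, threshold = 0.5) {
  scores <- vapply(results, function(r) {
    if (is.numeric(r)) r else r$score
  }, numeric(1))
  scores > threshold
}
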
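## Pathway thermodynamics: species are resolved to compounds of a pluggable
## formation-energy provider through a fixed matching cascade, the pathway is
## collapsed into a global pseudo-reaction by a stoichiometric-multiplier
## linear program, and Gibbs free energies are computed for reactions and for
## the pseudo-reaction.

#' Table-backed formation-energy provider
#'
#' Provider over a TSV table with columns `provider_key`, `dg_kj_mol` and
#' optionally `uncertainty`. Keys may be species ids, InChIKeys, InChIs or
#' SMILES; the matching cascade of [lookup_compound()] decides which rung a
#' key is hit on.
#'
#' @param path TSV file path, or a data frame with those columns.
#' @return an object of class `rp_formation_provider` with elements `keys`,
#'   `dg_of(key)` and table order preserved (first match wins on prefix
#'   lookups).
#' @export
formation_provider <- function(path) {
  df <- if (is.data.frame(path)) path else {
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
  if (!all(c("provider_key", "dg_kj_mol") %in% names(df))) {
    stop("formation table needs columns provider_key and dg_kj_mol")
  }
  if (!("uncertainty" %in% names(df))) df$uncertainty <- NA_real_
  keys <- as.character(df$provider_key)
  dg <- stats::setNames(as.numeric(df$dg_kj_mol), keys)
  unc <- stats::setNames(as.numeric(df$uncertainty), keys)
  structure(
    list(keys = keys,
         dg_of = function(key) {
           if (!(key %in% keys)) stop(sprintf("unknown provider key '%s'", key))
           list(value = unname(dg[[key]]),
                uncertainty = if (is.na(unc[[key]])) NULL else unname(unc[[key]]))
         }),
    class = "rp_formation_provider"
  )
}

#' Resolve a species to a provider compound
#'
#' Matching cascade, stopping at the first hit: species id, InChIKey, InChI,
#' SMILES, then — as a last resort — the first provider key whose first
#' InChIKey block (14 characters) equals the species' first block (the first
#' such key in table order is taken), and finally a user-supplied
#' substitution.
#'
#' @param s an `rp_species`.
#' @param provider an `rp_formation_provider`.
#' @param substitutions named character vector or list, species id to
#'   provider key.
#' @return `NULL` when unresolved, else a list with `provider_key` and
#'   `matched_by` (one of `id`, `inchikey`, `inchi`, `smiles`,
#'   `inchikey_block1`, `substitution`).
#' @export
lookup_compound <- function(s, provider, substitutions = list()) {
  keys <- provider$keys
  hit <- function(k, by) list(provider_key = k, matched_by = by)
  if (!is.null(s$id) && s$id %in% keys) return(hit(s$id, "id"))
  if (!is.null(s$inchikey) && s$inchikey %in% keys) return(hit(s$inchikey, "inchikey"))
  if (!is.null(s$inchi) && s$inchi %in% keys) return(hit(s$inchi, "inchi"))
  if (!is.null(s$smiles) && s$smiles %in% keys) return(hit(s$smiles, "smiles"))
  if (!is.null(s$inchikey)) {
    block <- inchikey_block1(s$inchikey)
    cand <- keys[is_inchikey(keys) & inchikey_block1(keys) == block]
    if (length(cand)) return(hit(cand[[1]], "inchikey_block1"))
  }
  sub <- substitutions[[s$id]]
  if (!is.null(sub)) {
    if (!(sub %in% keys)) {
      stop(sprintf("substitution for '%s' points at unknown provider key '%s'",
                   s$id, sub))
    }
    return(hit(sub, "substitution"))
  }
  NULL
}

## Intermediates: species produced by at least one pathway reaction and
## consumed by at least one, excluding the target and chassis species.
pathway_intermediates <- function(p, chassis_species = character()) {
  produced <- unique(unlist(lapply(p$reactions, function(r) names(r$products))))
  consumed <- unique(unlist(lapply(p$reactions, function(r) names(r$reactants))))
  setdiff(intersect(produced, consumed), c(p$target_id, chassis_species))
}

#' Build the global pseudo-reaction of a pathway
#'
#' Finds stoichiometric multipliers, one per reaction, such that every
#' pathway intermediate cancels exactly in the multiplier-weighted sum of
#' the reactions, yielding a single net reaction from chassis substrates to
#' the target. The multipliers solve the linear program
#' minimize `c' x` subject to `A x = 0`, `x >= 1`, where `A` is the
#' intermediates-by-reactions net stoichiometric matrix and `c` places 1 on
#' every target-producing reaction. A second phase minimizes the total sum
#' of multipliers at the fixed optimum, which makes the reported solution the
#' minimal-scale one and deterministic.
#'
#' @param p an `rp_pathway`.
#' @param chassis_species character vector of species ids present in the
#'   chassis; these are never constrained to cancel.
#' @return list with `multipliers` (named by reaction id), `net` (an
#'   `rp_reaction` holding the pseudo-reaction; species with net
#'   stoichiometry below 1e-9 are dropped) and `intermediates`.
#' @export
build_pseudo_reaction <- function(p, chassis_species = character()) {
  rids <- names(p$reactions)
  inter <- pathway_intermediates(p, chassis_species)
  n <- length(rids)

  net_coeff <- function(r, sid) {
    (if (sid %in% names(r$products)) r$products[[sid]] else 0) -
      (if (sid %in% names(r$reactants)) r$reactants[[sid]] else 0)
  }
  A <- matrix(0, length(inter), n, dimnames = list(inter, rids))
  for (i in seq_along(inter)) {
    for (j in seq_len(n)) A[i, j] <- net_coeff(p$reactions[[j]], inter[i])
  }
  cvec <- vapply(p$reactions, function(r) as.numeric(p$target_id %in% names(r$products)),
                 numeric(1))

  ub <- rep(Inf, n)
  sol <- solve_lp(cvec, Aeq = A, beq = rep(0, length(inter)),
                  lb = rep(1, n), ub = ub, maximize = FALSE)
  if (sol$status != "optimal") {
    ## name the intermediates that cannot cancel: those needing a multiplier
    ## below 1 or with single-signed coefficients
    bad <- inter[apply(A, 1, function(row) all(row >= 0) || all(row <= 0))]
    stop(sprintf("pseudo-reaction infeasible: intermediates cannot cancel%s",
                 if (length(bad)) paste0(" (", paste(bad, collapse = ", "), ")") else ""))
  }
  ## tie-break: among optima, take the componentwise smallest total scale
  sol2 <- solve_lp(rep(1, n),
                   Aeq = rbind(A, cvec),
                   beq = c(rep(0, length(inter)), sol$value),
                   lb = rep(1, n), ub = ub, maximize = FALSE)
  x <- if (sol2$status == "optimal") sol2$x else sol$x
  names(x) <- rids

  ## multiplier-weighted net reaction
  all_sp <- unique(unlist(lapply(p$reactions, function(r)
    c(names(r$reactants), names(r$products)))))
  net <- stats::setNames(numeric(length(all_sp)), all_sp)
  for (j in seq_len(n)) {
    r <- p$reactions[[j]]
    for (sid in names(r$reactants)) net[sid] <- net[sid] - x[j] * r$reactants[[sid]]
    for (sid in names(r$products)) net[sid] <- net[sid] + x[j] * r$products[[sid]]
  }
  net <- net[abs(net) >= STOICH_TOL]
  if (any(abs(net[names(net) %in% inter]) >= STOICH_TOL)) {
    stop("internal error: intermediates did not cancel in the pseudo-reaction")
  }
  net_rxn <- reaction_record(
    id = paste0(p$id, "__pseudo"),
    reactants = -net[net < 0],
    products = net[net > 0]
  )
  list(multipliers = x, net = net_rxn, intermediates = inter)
}

#' Gibbs free energy of one reaction
#'
#' Resolves every participating species through [lookup_compound()]; when all
#' resolve, the reaction energy is the stoichiometry-weighted difference of
#' formation energies (products minus reactants). When any species is
#' unresolved and unsubstituted the reaction has no thermodynamic value and
#' `NULL` is returned.
#'
#' @param r an `rp_reaction`.
#' @param species named list of `rp_species` covering the participants.
#' @param provider an `rp_formation_provider`.
#' @param substitutions named map, species id to provider key.
#' @return list with `value`, `uncertainty` (kJ/mol; uncertainty `NULL` when
#'   any participant lacks one) and `substituted` (ids resolved through the
#'   substitution rung), or `NULL`.
#' @export
reaction_dg <- function(r, species, provider, substitutions = list()) {
  participants <- c(names(r$reactants), names(r$products))
  coeffs <- c(-unname(r$reactants), unname(r$products))
  value <- 0
  var <- 0
  has_unc <- TRUE
  substituted <- character()
  for (k in seq_along(participants)) {
    sid <- participants[k]
    sp <- species[[sid]] %||% species_record(sid)
    ref <- lookup_compound(sp, provider, substitutions)
    if (is.null(ref)) return(NULL)
    if (ref$matched_by == "substitution") substituted <- c(substituted, sid)
    est <- provider$dg_of(ref$provider_key)
    value <- value + coeffs[k] * est$value
    if (is.null(est$uncertainty)) has_unc <- FALSE
    else var <- var + (coeffs[k] * est$uncertainty)^2
  }
  list(value = value, uncertainty = if (has_unc) sqrt(var) else NULL,
       substituted = unique(substituted))
}

#' Gibbs free energy of a whole pathway
#'
#' Builds the global pseudo-reaction with [build_pseudo_reaction()] and
#' evaluates its Gibbs energy with [reaction_dg()].
#'
#' @inheritParams reaction_dg
#' @param p an `rp_pathway`.
#' @param chassis_species species never constrained to cancel.
#' @return as [reaction_dg()]: a list or `NULL` when any net-reaction species
#'   is unresolved.
#' @export
pathway_dg <- function(p, provider, substitutions = list(),
                       chassis_species = character()) {
  pseudo <- build_pseudo_reaction(p, chassis_species)
  reaction_dg(pseudo$net, p$species, provider, substitutions)
}

#' Annotate a pathway with thermodynamic values
#'
#' Computes per-reaction energies and the pathway energy, stores them on the
#' records (`dg_prime`, `dg_uncertainty`, property `pathway_dg`) and records
#' substituted species in the `rp_thermo_substituted_species` group.
#'
#' @inheritParams pathway_dg
#' @return the annotated `rp_pathway`.
#' @export
annotate_thermo <- function(p, provider, substitutions = list(),
                            chassis_species = character()) {
  subs_used <- character()
  for (rid in names(p$reactions)) {
    est <- reaction_dg(p$reactions[[rid]], p$species, provider, substitutions)
    if (!is.null(est)) {
      p$reactions[[rid]]$dg_prime <- est$value
      p$reactions[[rid]]$dg_uncertainty <- est$uncertainty
      subs_used <- union(subs_used, est$substituted)
    }
  }
  est <- pathway_dg(p, provider, substitutions, chassis_species)
  if (!is.null(est)) {
    p$properties$pathway_dg <- est$value
    subs_used <- union(subs_used, est$substituted)
  }
  if (length(subs_used)) {
    p$groups$rp_thermo_substituted_species <-
      union(p$groups$rp_thermo_substituted_species %||% character(), subs_used)
  }
  p
}
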
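## Fraction-of-reaction flux balance analysis: the biomass flux is pinned to a
## fraction of its unconstrained optimum before the target production flux is
## maximized, emulating the growth burden of expressing a heterologous
## pathway.

#' Merge a heterologous pathway into a chassis model
#'
#' Adds the pathway's reactions and any new species to the chassis, plus an
#' irreversible sink reaction for the target (`target -> `, bounds
#' \[0, 1000\]). Orphan species — species absent from the chassis that end up
#' only consumed or only produced in the merged model (typically cofactors
#' with no chassis counterpart) — are excluded from mass balance and listed
#' in the model's `ignored_species`; pathway-internal intermediates, which
#' are both produced and consumed, stay balanced.
#'
#' @param model an `rp_chassis`.
#' @param p an `rp_pathway`.
#' @return an `rp_chassis` with the pathway merged, the target sink added
#'   (id `SINK_<target>`), and `ignored_species` populated.
#' @export
merge_pathway <- function(model, p) {
  reactions <- model$reactions
  species <- model$species
  for (r in p$reactions) {
    if (r$id %in% names(reactions)) {
      old <- reactions[[r$id]]
      if (!identical(reaction_signature(old, species),
                     reaction_signature(r, p$species))) {
        stop(sprintf("merge conflict: reaction '%s' exists with a different definition", r$id))
      }
      next  # identical duplicate, keep once
    }
    reactions[[r$id]] <- r
  }
  for (sid in names(p$species)) {
    if (!(sid %in% names(species))) species[[sid]] <- p$species[[sid]]
  }
  sink_id <- paste0("SINK_", p$target_id)
  if (!(sink_id %in% names(reactions))) {
    ## boundary pseudo-species keeps the record two-sided; its mass balance is
    ## always relaxed below
    bnd <- paste0(p$target_id, "_b")
    species[[bnd]] <- species_record(bnd, name = "sink boundary")
    reactions[[sink_id]] <- reaction_record(
      sink_id,
      reactants = stats::setNames(1, p$target_id),
      products = stats::setNames(1, bnd),
      lower_bound = 0, upper_bound = 1000)
  }

  ## orphan detection on the merged network
  consumed <- unique(unlist(lapply(reactions, function(r) names(r$reactants))))
  produced <- unique(unlist(lapply(reactions, function(r) names(r$products))))
  new_species <- setdiff(names(species), names(model$species))
  orphans <- setdiff(new_species, intersect(consumed, produced))
  orphans <- union(orphans, paste0(p$target_id, "_b"))

  chassis_model(
    id = paste(model$id, p$id, sep = "__"),
    species = species, reactions = reactions,
    biomass_reaction_id = model$biomass_reaction_id,
    taxon_id = model$taxon_id,
    ignored_species = union(model$ignored_species, orphans)
  )
}

## Stoichiometric matrix (balanced species x reactions) of a chassis model.
stoich_matrix <- function(model) {
  balanced <- setdiff(names(model$species), model$ignored_species)
  S <- matrix(0, length(balanced), length(model$reactions),
              dimnames = list(balanced, names(model$reactions)))
  for (r in model$reactions) {
    for (sid in names(r$reactants)) {
      if (sid %in% balanced) S[sid, r$id] <- S[sid, r$id] - r$reactants[[sid]]
    }
    for (sid in names(r$products)) {
      if (sid %in% balanced) S[sid, r$id] <- S[sid, r$id] + r$products[[sid]]
    }
  }
  S
}

#' Maximize one reaction's flux in a chassis model
#'
#' Plain flux balance analysis: maximize the flux of `reaction_id` subject to
#' steady state (`S v = 0` over balanced species) and the model's flux
#' bounds.
#'
#' @param model an `rp_chassis`.
#' @param reaction_id reaction whose flux is maximized.
#' @return list with `objective` (optimal flux) and `status`.
#' @export
optimize_flux <- function(model, reaction_id) {
  if (!(reaction_id %in% names(model$reactions))) {
    stop(sprintf("unknown reaction '%s'", reaction_id))
  }
  S <- stoich_matrix(model)
  lb <- vapply(model$reactions, `[[`, numeric(1), "lower_bound")
  ub <- vapply(model$reactions, `[[`, numeric(1), "upper_bound")
  obj <- as.numeric(names(model$reactions) == reaction_id)
  sol <- solve_lp(obj, Aeq = S, beq = rep(0, nrow(S)), lb = lb, ub = ub,
                  maximize = TRUE)
  if (sol$status != "optimal") stop("flux balance problem is infeasible")
  list(objective = sol$value, status = sol$status)
}

#' Fraction-of-reaction FBA
#'
#' Four steps: (1) maximize the biomass reaction and record its optimum B;
#' (2) fix both biomass bounds to `fraction * B`; (3) maximize the target
#' sink flux; (4) restore every modified bound before returning. The result
#' is also written into the pathway's properties (`target_flux`,
#' `biomass_optimum`, `fba_fraction`) and the orphan species into its
#' `rp_fba_ignored_species` group.
#'
#' @param model an `rp_chassis` (the un-merged chassis).
#' @param p an `rp_pathway`.
#' @param fraction biomass fraction in (0, 1\]; default 0.75.
#' @return list with `result` (fields `biomass_optimum`, `fraction`,
#'   `target_flux`, `ignored_species`), `pathway` (annotated copy of `p`) and
#'   `model` (the merged model, bounds untouched).
#' @export
fraction_of_reaction_fba <- function(model, p, fraction = 0.75) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must be a single number in (0, 1]")
  }
  merged <- merge_pathway(model, p)
  sink_id <- paste0("SINK_", p$target_id)
  bounds_before <- lapply(merged$reactions, function(r)
    c(r$lower_bound, r$upper_bound))

  biomass <- optimize_flux(merged, merged$biomass_reaction_id)$objective

  pinned <- merged
  pinned$reactions[[merged$biomass_reaction_id]]$lower_bound <- fraction * biomass
  pinned$reactions[[merged$biomass_reaction_id]]$upper_bound <- fraction * biomass
  target_flux <- optimize_flux(pinned, sink_id)$objective

  ## restore: `merged` was never mutated (copy-on-modify), assert anyway
  bounds_after <- lapply(merged$reactions, function(r)
    c(r$lower_bound, r$upper_bound))
  stopifnot(identical(bounds_before, bounds_after))

  result <- list(biomass_optimum = biomass, fraction = fraction,
                 target_flux = target_flux,
                 ignored_species = merged$ignored_species)
  p$properties$biomass_optimum <- biomass
  p$properties$fba_fraction <- fraction
  p$properties$target_flux <- target_flux
  p$groups$rp_fba_ignored_species <-
    intersect(merged$ignored_species, names(p$species))
  list(result = result, pathway = p, model = merged)
}
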
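#' Chemical species record
#'
#' A species participating in a pathway or chassis model, optionally carrying
#' structure identifiers (InChI, SMILES, InChIKey), MIRIAM-style
#' cross-references and a formation energy.
#'
#' @param id identifier string.
#' @param name free-text name.
#' @param inchi,smiles,inchikey optional structure identifiers. An InChIKey,
#'   when given, must follow the 14-10-1 block layout.
#' @param cross_refs character vector of database-qualified identifiers,
#'   e.g. `"metanetx.chemical:MNXM4"`.
#' @param formation_dg optional standard formation energy (kJ/mol).
#' @return an object of class `rp_species`.
#' @export
species_record <- function(id, name = id, inchi = NULL, smiles = NULL,
                           inchikey = NULL, cross_refs = character(),
                           formation_dg = NULL) {
  if ((is.null(id) || !nzchar(id)) && is.null(inchi) && is.null(smiles) &&
      is.null(inchikey)) {
    stop("species needs at least one of id, inchi, smiles, inchikey")
  }
  if (!is.null(inchikey) && !is_inchikey(inchikey)) {
    stop(sprintf("malformed InChIKey for species '%s': %s", id, inchikey))
  }
  structure(
    list(id = id, name = name, inchi = inchi, smiles = smiles,
         inchikey = inchikey, cross_refs = cross_refs,
         formation_dg = formation_dg),
    class = "rp_species"
  )
}

#' Reaction record
#'
#' A (possibly bounded) stoichiometric reaction. Species appearing on both
#' sides are netted out; a species with equal stoichiometry on both sides is
#' removed entirely.
#'
#' @param id identifier string.
#' @param reactants,products named numeric vectors, species id to positive
#'   stoichiometry. Both must be non-empty after netting.
#' @param ec_numbers character vector of EC numbers.
#' @param rule_id,template_id optional reaction-rule provenance.
#' @param rule_score optional enzyme-availability score in \[0, 1\].
#' @param dg_prime,dg_uncertainty optional Gibbs energy (kJ/mol).
#' @param lower_bound,upper_bound flux bounds (mmol/gDCW/h by convention);
#'   used when the reaction lives in a chassis model.
#' @return an object of class `rp_reaction`.
#' @export
reaction_record <- function(id, reactants, products, ec_numbers = character(),
                            rule_id = NULL, template_id = NULL,
                            rule_score = NULL, dg_prime = NULL,
                            dg_uncertainty = NULL,
                            lower_bound = 0, upper_bound = 1000) {
  reactants <- reactants[reactants != 0]
  products <- products[products != 0]
  if (any(reactants < 0) || any(products < 0)) {
    stop(sprintf("reaction '%s': stoichiometries must be positive", id))
  }
  if (length(reactants) == 0 || length(products) == 0) {
    stop(sprintf("reaction '%s': reactants and products must be non-empty", id))
  }
  ## net out species present on both sides; a reaction whose sides net to
  ## nothing (e.g. the identity A -> A) stays constructible as a degenerate
  ## record with empty sides
  shared <- intersect(names(reactants), names(products))
  for (s in shared) {
    net <- products[[s]] - reactants[[s]]
    reactants <- reactants[names(reactants) != s]
    products <- products[names(products) != s]
    if (net > STOICH_TOL) products[[s]] <- net
    if (net < -STOICH_TOL) reactants[[s]] <- -net
  }
  if (xor(length(reactants) == 0, length(products) == 0)) {
    stop(sprintf("reaction '%s': netting left only one side populated", id))
  }
  if (!is.null(rule_score) && (rule_score < 0 || rule_score > 1)) {
    stop(sprintf("reaction '%s': rule_score must lie in [0, 1]", id))
  }
  if (lower_bound > upper_bound) {
    stop(sprintf("reaction '%s': lower bound exceeds upper bound", id))
  }
  structure(
    list(id = id,
         reactants = reactants[order(names(reactants))],
         products = products[order(names(products))],
         ec_numbers = ec_numbers, rule_id = rule_id,
         template_id = template_id, rule_score = rule_score,
         dg_prime = dg_prime, dg_uncertainty = dg_uncertainty,
         lower_bound = lower_bound, upper_bound = upper_bound),
    class = "rp_reaction"
  )
}

#' Heterologous pathway record
#'
#' An ordered list of heterologous reactions producing a target species,
#' together with the species they reference, named annotation groups and
#' computed properties (pathway Gibbs energy, target flux, scores).
#'
#' The three canonical groups are `rp_pathway` (the heterologous reactions),
#' `rp_fba_ignored_species` and `rp_thermo_substituted_species`.
#'
#' @param id pathway identifier.
#' @param reactions list of [reaction_record()] objects, substrate side first,
#'   target-producing reaction last.
#' @param target_id id of the target species.
#' @param species list of [species_record()] objects covering every species
#'   referenced by the reactions.
#' @param groups named list of character vectors (group name to member ids).
#' @param properties named list of computed properties.
#' @return an object of class `rp_pathway`.
#' @export
pathway_record <- function(id, reactions, target_id, species,
                           groups = list(), properties = list()) {
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  names(species) <- vapply(species, `[[`, character(1), "id")
  if (!("rp_pathway" %in% names(groups))) {
    groups$rp_pathway <- names(reactions)
  }
  p <- structure(
    list(id = id, reactions = reactions, target_id = target_id,
         species = species, groups = groups, properties = properties),
    class = "rp_pathway"
  )
  validate_pathway(p)
  p
}

#' Validate a pathway record
#'
#' Checks referential integrity: every species referenced by a reaction must
#' exist in the species table, group members must reference existing ids, and
#' the target must be produced by at least one reaction.
#'
#' @param p an `rp_pathway`.
#' @return `p`, invisibly; errors list the offending ids.
#' @export
validate_pathway <- function(p) {
  refd <- unique(unlist(lapply(p$reactions, function(r) {
    c(names(r$reactants), names(r$products))
  })))
  missing_sp <- setdiff(refd, names(p$species))
  if (length(missing_sp)) {
    stop(sprintf("pathway '%s': species referenced but not defined: %s",
                 p$id, paste(missing_sp, collapse = ", ")))
  }
  produced <- unique(unlist(lapply(p$reactions, function(r) names(r$products))))
  if (!(p$target_id %in% produced)) {
    stop(sprintf("pathway '%s': target '%s' is not produced by any reaction",
                 p$id, p$target_id))
  }
  known <- c(names(p$species), names(p$reactions))
  for (g in names(p$groups)) {
    bad <- setdiff(p$groups[[g]], known)
    if (length(bad)) {
      stop(sprintf("pathway '%s': group '%s' references unknown ids: %s",
                   p$id, g, paste(bad, collapse = ", ")))
    }
  }
  invisible(p)
}

#' Chassis genome-scale model
#'
#' A stoichiometric model of the host organism with flux bounds, a designated
#' biomass reaction and an NCBI taxonomy id.
#'
#' @param id model identifier.
#' @param species list of [species_record()].
#' @param reactions list of [reaction_record()] carrying bounds.
#' @param biomass_reaction_id id of the biomass reaction (must exist).
#' @param taxon_id integer NCBI taxonomy id of the organism.
#' @param ignored_species character vector of boundary species excluded from
#'   mass balance (populated by [merge_pathway()]).
#' @return an object of class `rp_chassis`.
#' @export
chassis_model <- function(id, species, reactions, biomass_reaction_id,
                          taxon_id = NA_integer_,
                          ignored_species = character()) {
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  names(species) <- vapply(species, `[[`, character(1), "id")
  if (!(biomass_reaction_id %in% names(reactions))) {
    stop(sprintf("biomass reaction '%s' not found in model", biomass_reaction_id))
  }
  for (r in reactions) {
    if (r$lower_bound > r$upper_bound) {
      stop(sprintf("reaction '%s': lower bound exceeds upper bound", r$id))
    }
  }
  structure(
    list(id = id, species = species, reactions = reactions,
         biomass_reaction_id = biomass_reaction_id,
         taxon_id = as.integer(taxon_id),
         ignored_species = ignored_species),
    class = "rp_chassis"
  )
}

#' @export
print.rp_pathway <- function(x, ...) {
  cat(sprintf("<rp_pathway> %s: %d reactions -> %s\n",
              x$id, length(x$reactions), x$target_id))
  for (nm in names(x$properties)) {
    v <- x$properties[[nm]]
    if (is.numeric(v)) cat(sprintf("  %s: %.4g\n", nm, v))
  }
  invisible(x)
}

#' @export
print.rp_chassis <- function(x, ...) {
  cat(sprintf("<rp_chassis> %s: %d species, %d reactions, biomass=%s, taxon=%s\n",
              x$id, length(x$species), length(x$reactions),
              x$biomass_reaction_id, x$taxon_id))
  invisible(x)
}

#' @export
print.rp_reaction <- function(x, ...) {
  side <- function(v) paste(sprintf("%s %s", format_stoich(unname(v)), names(v)),
                            collapse = " + ")
  cat(sprintf("<rp_reaction> %s: %s --> %s\n", x$id,
              side(x$reactants), side(x$products)))
  invisible(x)
}

## Content signature of a reaction under structure-based species identity
## (InChIKey when present, else id); used for duplicate removal.
reaction_signature <- function(r, species) {
  key_of <- function(sid) {
    sp <- species[[sid]]
    if (!is.null(sp) && !is.null(sp$inchikey)) sp$inchikey else sid
  }
  fmt_side <- function(v) {
    keys <- vapply(names(v), key_of, character(1))
    o <- order(keys)
    paste(sprintf("%s*%s", format_stoich(round(unname(v)[o] / STOICH_TOL) * STOICH_TOL),
                  keys[o]), collapse = "+")
  }
  paste(fmt_side(r$reactants), fmt_side(r$products), sep = ">>")
}
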
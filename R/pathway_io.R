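## SBML Level 3 Version 1 dialect with the groups and fbc (flux-bounds)
## packages. Chemical structures, rule provenance and computed properties are
## carried in a dedicated annotation namespace so that standard SBML readers
## ignore them.

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
SBML_GROUPS_NS <- "http://www.sbml.org/sbml/level3/version1/groups/version1"

#' Annotation namespace URI
#'
#' URI of the XML namespace housing the non-standard annotations (structures,
#' rule provenance, computed properties). Override with
#' `options(pathranker.annotation_namespace = ...)` when interoperating with
#' documents that use a different URI for the same element layout.
#'
#' @return a single string.
#' @export
annotation_namespace <- function() {
  getOption("pathranker.annotation_namespace",
            "https://pathranker.org/schema/v1")
}

sbml_ns_map <- function() {
  c(s = SBML_CORE_NS, fbc = SBML_FBC_NS, g = SBML_GROUPS_NS,
    pr = annotation_namespace())
}

## ---- writing ---------------------------------------------------------------

species_annotation_lines <- function(sp, indent) {
  body <- character()
  tag <- function(name, value) {
    if (!is.null(value) && length(value)) {
      sprintf("%s  <pr:%s>%s</pr:%s>", indent, name, xml_escape(as.character(value)), name)
    } else character()
  }
  body <- c(body, tag("inchi", sp$inchi), tag("smiles", sp$smiles),
            tag("inchikey", sp$inchikey))
  if (!is.null(sp$formation_dg)) {
    body <- c(body, tag("formation_dg", as.character(sp$formation_dg)))
  }
  for (xr in sp$cross_refs) body <- c(body, tag("xref", xr))
  if (!length(body)) return(character())
  c(sprintf("%s<annotation>", substr(indent, 1, nchar(indent) - 2)),
    sprintf("%s<pr:molecule xmlns:pr=\"%s\">", indent, annotation_namespace()),
    body,
    sprintf("%s</pr:molecule>", indent),
    sprintf("%s</annotation>", substr(indent, 1, nchar(indent) - 2)))
}

reaction_annotation_lines <- function(r, indent) {
  body <- character()
  tag <- function(name, value) {
    if (!is.null(value) && length(value)) {
      sprintf("%s  <pr:%s>%s</pr:%s>", indent, name, xml_escape(as.character(value)), name)
    } else character()
  }
  ## energies and scores keep full double precision; only stoichiometries
  ## follow the 6-significant-digit convention
  body <- c(body, tag("rule_id", r$rule_id), tag("template_id", r$template_id))
  if (!is.null(r$rule_score)) body <- c(body, tag("rule_score", as.character(r$rule_score)))
  if (!is.null(r$dg_prime)) body <- c(body, tag("dg_prime", as.character(r$dg_prime)))
  if (!is.null(r$dg_uncertainty)) body <- c(body, tag("dg_uncertainty", as.character(r$dg_uncertainty)))
  for (ec in r$ec_numbers) body <- c(body, tag("ec", ec))
  if (!length(body)) return(character())
  c(sprintf("%s<annotation>", substr(indent, 1, nchar(indent) - 2)),
    sprintf("%s<pr:reaction xmlns:pr=\"%s\">", indent, annotation_namespace()),
    body,
    sprintf("%s</pr:reaction>", indent),
    sprintf("%s</annotation>", substr(indent, 1, nchar(indent) - 2)))
}

species_lines <- function(species, boundary = character()) {
  out <- c("    <listOfSpecies>")
  for (sid in sort(names(species))) {
    sp <- species[[sid]]
    ann <- species_annotation_lines(sp, "          ")
    open <- sprintf(paste0(
      "      <species id=\"%s\" name=\"%s\" compartment=\"c\" ",
      "hasOnlySubstanceUnits=\"false\" boundaryCondition=\"%s\" ",
      "constant=\"false\""), xml_escape(sp$id), xml_escape(sp$name %||% sp$id),
      if (sid %in% boundary) "true" else "false")
    if (length(ann)) {
      out <- c(out, paste0(open, ">"), ann, "      </species>")
    } else {
      out <- c(out, paste0(open, "/>"))
    }
  }
  c(out, "    </listOfSpecies>")
}

side_lines <- function(v, tagname) {
  if (!length(v)) return(character())
  c(sprintf("        <%s>", tagname),
    sprintf("          <speciesReference species=\"%s\" stoichiometry=\"%s\" constant=\"true\"/>",
            xml_escape(names(v)), format_stoich(unname(v))),
    sprintf("        </%s>", tagname))
}

reaction_lines <- function(reactions, with_bounds) {
  out <- c("    <listOfReactions>")
  for (r in reactions) {
    bound_attr <- if (with_bounds) {
      sprintf(" fbc:lowerFluxBound=\"pr_lb_%s\" fbc:upperFluxBound=\"pr_ub_%s\"",
              r$id, r$id)
    } else ""
    rev <- if (with_bounds && r$lower_bound < 0) "true" else "false"
    out <- c(out,
      sprintf("      <reaction id=\"%s\" reversible=\"%s\" fast=\"false\"%s>",
              xml_escape(r$id), rev, bound_attr),
      reaction_annotation_lines(r, "          "),
      side_lines(r$reactants, "listOfReactants"),
      side_lines(r$products, "listOfProducts"),
      "      </reaction>")
  }
  c(out, "    </listOfReactions>")
}

group_lines <- function(groups) {
  nm <- names(groups)
  nm <- c(intersect("rp_pathway", nm), sort(setdiff(nm, "rp_pathway")))
  nm <- nm[vapply(nm, function(g) length(groups[[g]]) > 0, logical(1))]
  if (!length(nm)) return(character())
  out <- "    <groups:listOfGroups>"
  for (g in nm) {
    out <- c(out,
      sprintf("      <groups:group groups:id=\"%s\" groups:kind=\"collection\">", g),
      "        <groups:listOfMembers>",
      sprintf("          <groups:member groups:idRef=\"%s\"/>", xml_escape(groups[[g]])),
      "        </groups:listOfMembers>",
      "      </groups:group>")
  }
  c(out, "    </groups:listOfGroups>")
}

sbml_header <- function() {
  c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"", SBML_CORE_NS, "\"",
           " xmlns:fbc=\"", SBML_FBC_NS, "\"",
           " xmlns:groups=\"", SBML_GROUPS_NS, "\"",
           " level=\"3\" version=\"1\"",
           " fbc:required=\"false\" groups:required=\"false\">"))
}

#' Write a pathway as an enriched SBML document
#'
#' Emits SBML Level 3 Version 1 with the groups package. Structures, rule
#' provenance and computed properties are written in the annotation namespace
#' (see [annotation_namespace()]); the named groups (`rp_pathway`,
#' `rp_fba_ignored_species`, `rp_thermo_substituted_species`) are emitted
#' when non-empty. Output is deterministic: writing the same record twice
#' yields byte-identical documents.
#'
#' @param p an `rp_pathway` (validated before writing).
#' @param path optional file path; when `NULL` the document is returned as a
#'   single string.
#' @return the document string (invisibly when `path` is given).
#' @export
write_pathway <- function(p, path = NULL) {
  validate_pathway(p)
  props <- character()
  if (length(p$properties)) {
    for (nm in sort(names(p$properties))) {
      props <- c(props, sprintf(
        "        <pr:property name=\"%s\" value=\"%s\"/>",
        xml_escape(nm), xml_escape(as.character(p$properties[[nm]]))))
    }
  }
  lines <- c(
    sbml_header(),
    sprintf("  <model id=\"%s\" fbc:strict=\"false\">", xml_escape(p$id)),
    "    <annotation>",
    sprintf("      <pr:pathway xmlns:pr=\"%s\" target=\"%s\">",
            annotation_namespace(), xml_escape(p$target_id)),
    props,
    "      </pr:pathway>",
    "    </annotation>",
    "    <listOfCompartments>",
    "      <compartment id=\"c\" constant=\"true\"/>",
    "    </listOfCompartments>",
    species_lines(p$species),
    reaction_lines(p$reactions, with_bounds = FALSE),
    group_lines(p$groups),
    "  </model>",
    "</sbml>")
  doc <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(doc)
  writeLines(doc, path, sep = "")
  invisible(doc)
}

#' Write a chassis model as SBML with flux bounds
#'
#' Emits SBML Level 3 Version 1 with the flux-bounds package: per-reaction
#' bound parameters, and an active objective pointing at the biomass reaction.
#' The taxonomy id travels in the annotation namespace.
#'
#' @param m an `rp_chassis`.
#' @inheritParams write_pathway
#' @return the document string (invisibly when `path` is given).
#' @export
write_chassis <- function(m, path = NULL) {
  par_lines <- c("    <listOfParameters>")
  for (r in m$reactions) {
    par_lines <- c(par_lines,
      sprintf("      <parameter id=\"pr_lb_%s\" value=\"%s\" constant=\"true\"/>",
              r$id, format_stoich(r$lower_bound)),
      sprintf("      <parameter id=\"pr_ub_%s\" value=\"%s\" constant=\"true\"/>",
              r$id, format_stoich(r$upper_bound)))
  }
  par_lines <- c(par_lines, "    </listOfParameters>")
  lines <- c(
    sbml_header(),
    sprintf("  <model id=\"%s\" fbc:strict=\"false\">", xml_escape(m$id)),
    "    <annotation>",
    sprintf("      <pr:chassis xmlns:pr=\"%s\" taxon_id=\"%s\"/>",
            annotation_namespace(), m$taxon_id),
    "    </annotation>",
    "    <listOfCompartments>",
    "      <compartment id=\"c\" constant=\"true\"/>",
    "    </listOfCompartments>",
    species_lines(m$species, boundary = m$ignored_species),
    par_lines,
    reaction_lines(m$reactions, with_bounds = TRUE),
    "    <fbc:listOfObjectives fbc:activeObjective=\"obj_biomass\">",
    "      <fbc:objective fbc:id=\"obj_biomass\" fbc:type=\"maximize\">",
    "        <fbc:listOfFluxObjectives>",
    sprintf("          <fbc:fluxObjective fbc:reaction=\"%s\" fbc:coefficient=\"1\"/>",
            xml_escape(m$biomass_reaction_id)),
    "        </fbc:listOfFluxObjectives>",
    "      </fbc:objective>",
    "    </fbc:listOfObjectives>",
    "  </model>",
    "</sbml>")
  doc <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(doc)
  writeLines(doc, path, sep = "")
  invisible(doc)
}

## ---- reading ---------------------------------------------------------------

read_sbml_doc <- function(document) {
  if (inherits(document, "xml_document")) return(document)
  if (is.raw(document)) return(xml2::read_xml(document))
  if (length(document) == 1 && !grepl("<", document, fixed = TRUE)) {
    return(xml2::read_xml(document))  # a path
  }
  xml2::read_xml(paste(document, collapse = "\n"))
}

xml_text1 <- function(node, xpath, ns) {
  hit <- xml2::xml_find_first(node, xpath, ns)
  if (inherits(hit, "xml_missing")) NULL else xml2::xml_text(hit)
}

parse_species_node <- function(node, ns) {
  id <- xml2::xml_attr(node, "id")
  name <- xml2::xml_attr(node, "name")
  dg <- xml_text1(node, "./s:annotation/pr:molecule/pr:formation_dg", ns)
  species_record(
    id = id,
    name = if (is.na(name)) id else name,
    inchi = xml_text1(node, "./s:annotation/pr:molecule/pr:inchi", ns),
    smiles = xml_text1(node, "./s:annotation/pr:molecule/pr:smiles", ns),
    inchikey = xml_text1(node, "./s:annotation/pr:molecule/pr:inchikey", ns),
    cross_refs = xml2::xml_text(
      xml2::xml_find_all(node, "./s:annotation/pr:molecule/pr:xref", ns)),
    formation_dg = if (is.null(dg)) NULL else as.numeric(dg)
  )
}

parse_side <- function(node, xpath, ns) {
  refs <- xml2::xml_find_all(node, xpath, ns)
  if (!length(refs)) return(numeric(0))
  stats::setNames(as.numeric(xml2::xml_attr(refs, "stoichiometry")),
                  xml2::xml_attr(refs, "species"))
}

parse_reaction_node <- function(node, ns, bounds = NULL) {
  num_or_null <- function(x) if (is.null(x)) NULL else as.numeric(x)
  lb <- 0; ub <- 1000
  if (!is.null(bounds)) {
    lb_ref <- xml2::xml_attr(node, "fbc:lowerFluxBound", ns)
    ub_ref <- xml2::xml_attr(node, "fbc:upperFluxBound", ns)
    if (!is.na(lb_ref) && lb_ref %in% names(bounds)) lb <- bounds[[lb_ref]]
    if (!is.na(ub_ref) && ub_ref %in% names(bounds)) ub <- bounds[[ub_ref]]
    if (is.na(lb_ref) && identical(xml2::xml_attr(node, "reversible"), "true")) {
      lb <- -1000
    }
  }
  if (lb > ub) {
    stop(sprintf("reaction '%s': lower flux bound %g exceeds upper bound %g",
                 xml2::xml_attr(node, "id"), lb, ub))
  }
  reaction_record(
    id = xml2::xml_attr(node, "id"),
    reactants = parse_side(node, "./s:listOfReactants/s:speciesReference", ns),
    products = parse_side(node, "./s:listOfProducts/s:speciesReference", ns),
    ec_numbers = xml2::xml_text(
      xml2::xml_find_all(node, "./s:annotation/pr:reaction/pr:ec", ns)),
    rule_id = xml_text1(node, "./s:annotation/pr:reaction/pr:rule_id", ns),
    template_id = xml_text1(node, "./s:annotation/pr:reaction/pr:template_id", ns),
    rule_score = num_or_null(xml_text1(node, "./s:annotation/pr:reaction/pr:rule_score", ns)),
    dg_prime = num_or_null(xml_text1(node, "./s:annotation/pr:reaction/pr:dg_prime", ns)),
    dg_uncertainty = num_or_null(xml_text1(node, "./s:annotation/pr:reaction/pr:dg_uncertainty", ns)),
    lower_bound = lb, upper_bound = ub
  )
}

parse_groups <- function(model, ns) {
  out <- list()
  for (g in xml2::xml_find_all(model, ".//g:listOfGroups/g:group", ns)) {
    gid <- xml2::xml_attr(g, "g:id", ns)
    out[[gid]] <- xml2::xml_attr(
      xml2::xml_find_all(g, "./g:listOfMembers/g:member", ns), "g:idRef", ns)
  }
  out
}

#' Read an enriched SBML pathway document
#'
#' Parses an SBML Level 3 document containing a group named `rp_pathway`; the
#' pathway's reactions are exactly the members of that group, in group order.
#' Custom annotations (structures, rule provenance, rule score, computed
#' properties) are recovered from the annotation namespace.
#'
#' @param document a file path, a string holding the XML, a raw vector, or a
#'   parsed `xml_document`.
#' @return an `rp_pathway`.
#' @export
read_pathway <- function(document) {
  doc <- read_sbml_doc(document)
  ns <- sbml_ns_map()
  model <- xml2::xml_find_first(doc, "./s:model", ns)
  if (inherits(model, "xml_missing")) stop("not an SBML document: no <model>")
  groups <- parse_groups(model, ns)
  if (!("rp_pathway" %in% names(groups))) {
    stop("document lacks the required group 'rp_pathway'")
  }
  species <- lapply(xml2::xml_find_all(model, ".//s:listOfSpecies/s:species", ns),
                    parse_species_node, ns = ns)
  names(species) <- vapply(species, `[[`, character(1), "id")
  rxn_nodes <- xml2::xml_find_all(model, ".//s:listOfReactions/s:reaction", ns)
  reactions <- lapply(rxn_nodes, parse_reaction_node, ns = ns)
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  ## pathway reactions are exactly the rp_pathway members, in group order
  reactions <- reactions[groups$rp_pathway]

  target <- xml2::xml_attr(
    xml2::xml_find_first(model, "./s:annotation/pr:pathway", ns), "target")
  if (is.na(target) || is.null(target)) {
    ## foreign document: the target is the unique species produced but never
    ## consumed by the pathway reactions
    produced <- unlist(lapply(reactions, function(r) names(r$products)))
    consumed <- unlist(lapply(reactions, function(r) names(r$reactants)))
    sinks <- setdiff(produced, consumed)
    if (length(sinks) != 1) {
      stop("cannot infer the target species: annotate the document or ensure a unique terminal product")
    }
    target <- sinks
  }
  properties <- list()
  for (pnode in xml2::xml_find_all(model, "./s:annotation/pr:pathway/pr:property", ns)) {
    val <- xml2::xml_attr(pnode, "value")
    num <- suppressWarnings(as.numeric(val))
    properties[[xml2::xml_attr(pnode, "name")]] <- if (is.na(num)) val else num
  }
  ## keep only species referenced by the pathway reactions
  refd <- unique(unlist(lapply(reactions, function(r)
    c(names(r$reactants), names(r$products)))))
  pathway_record(
    id = xml2::xml_attr(model, "id"),
    reactions = reactions,
    target_id = target,
    species = species[intersect(names(species), refd)],
    groups = groups,
    properties = properties
  )
}

#' Read a chassis model from SBML
#'
#' Imports species, reactions and flux bounds from an SBML Level 3 document
#' with the flux-bounds package. The biomass reaction is taken from
#' `biomass_hint` when given, otherwise from the document's active objective.
#'
#' @inheritParams read_pathway
#' @param biomass_hint optional reaction id overriding the declared objective.
#' @return an `rp_chassis`.
#' @export
read_chassis <- function(document, biomass_hint = NULL) {
  doc <- read_sbml_doc(document)
  ns <- sbml_ns_map()
  model <- xml2::xml_find_first(doc, "./s:model", ns)
  if (inherits(model, "xml_missing")) stop("not an SBML document: no <model>")
  par_nodes <- xml2::xml_find_all(model, ".//s:listOfParameters/s:parameter", ns)
  bounds <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                            xml2::xml_attr(par_nodes, "id"))
  sp_nodes <- xml2::xml_find_all(model, ".//s:listOfSpecies/s:species", ns)
  species <- lapply(sp_nodes, parse_species_node, ns = ns)
  boundary <- xml2::xml_attr(sp_nodes, "id")[
    xml2::xml_attr(sp_nodes, "boundaryCondition") == "true"]
  reactions <- lapply(
    xml2::xml_find_all(model, ".//s:listOfReactions/s:reaction", ns),
    parse_reaction_node, ns = ns, bounds = as.list(bounds))

  biomass <- biomass_hint
  if (is.null(biomass)) {
    active <- xml2::xml_attr(
      xml2::xml_find_first(model, ".//fbc:listOfObjectives", ns),
      "fbc:activeObjective", ns)
    fo <- xml2::xml_find_first(
      model, sprintf(".//fbc:objective[@fbc:id='%s']/fbc:listOfFluxObjectives/fbc:fluxObjective",
                     active), ns)
    if (!inherits(fo, "xml_missing")) {
      biomass <- xml2::xml_attr(fo, "fbc:reaction", ns)
    }
  }
  if (is.null(biomass) || is.na(biomass)) {
    stop("no biomass reaction resolvable: give biomass_hint or declare an objective")
  }
  taxon <- xml2::xml_attr(
    xml2::xml_find_first(model, "./s:annotation/pr:chassis", ns), "taxon_id")
  chassis_model(
    id = xml2::xml_attr(model, "id"),
    species = species, reactions = reactions,
    biomass_reaction_id = biomass,
    taxon_id = if (is.na(taxon) || is.null(taxon)) NA_integer_ else as.integer(taxon),
    ignored_species = boundary
  )
}
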
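## Self-contained fixture generators: toy chassis models, rule databases with
## matching master pathways, formation-energy tables and labeled pathway
## collections with a planted, tunable separation between positive and
## negative classes. Every generator is a pure function of its arguments and
## seed.

#' Fixture SMILES alphabet
#'
#' Fixed alphabet of 32 small alkane/alcohol/ether SMILES used to give
#' synthetic species real chemical structures, so circular fingerprints are
#' computed on genuine molecular graphs.
#'
#' @return character vector of length 32.
#' @export
fixture_smiles_alphabet <- function() {
  c("C", "CC", "CCC", "CCCC", "CCCCC", "CCCCCC", "CCCCCCC", "CCCCCCCC",
    "CC(C)C", "CC(C)CC", "CC(C)(C)C", "CCC(C)CC", "CC(C)C(C)C", "CCCC(C)C",
    "CO", "CCO", "CCCO", "CCCCO", "CCCCCO", "CCCCCCO",
    "CC(C)O", "CC(C)CO", "CC(C)(C)O", "CCC(O)CC",
    "OCCO", "OCCCO", "OCCCCO", "CC(O)CO",
    "COC", "CCOC", "CCOCC", "COCCO")
}

#' Deterministic synthetic InChIKey
#'
#' Hashes an arbitrary string into the 14-10-1 InChIKey block layout. The
#' result is a syntactically valid key that exercises structure-identity
#' logic without real chemistry; it is not the InChIKey of any actual
#' molecule.
#'
#' @param x character vector.
#' @return character vector of synthetic InChIKeys.
#' @export
synthetic_inchikey <- function(x) {
  letters_from <- function(s, salt, k) {
    h <- fnv1a32(paste0(s, "#", salt))
    out <- character(k)
    for (i in seq_len(k)) {
      out[i] <- LETTERS[(h %% 26) + 1]
      h <- mul32(h, 2654435761) %% 4294967296
      h <- bitwXor_dbl(h, fnv1a32(paste0(s, salt, i)))
    }
    paste(out, collapse = "")
  }
  vapply(x, function(s) {
    paste0(letters_from(s, "a", 14), "-", letters_from(s, "b", 10), "-N")
  }, character(1), USE.NAMES = FALSE)
}

fixture_species <- function(id, smiles = NULL) {
  species_record(id, smiles = smiles, inchikey = synthetic_inchikey(id))
}

#' Generate a toy chassis model
#'
#' A minimal feasible model: one uptake reaction feeding the first core
#' metabolite (bound 10 mmol/gDCW/h), a linear conversion chain through the
#' core, and a biomass reaction draining the last core metabolite. The
#' boundary species of the uptake and biomass reactions are excluded from
#' mass balance, so the biomass optimum is strictly positive (it equals the
#' uptake bound).
#'
#' @param n_core number of core metabolites (>= 2).
#' @param seed seed for the structure assignment.
#' @return an `rp_chassis` with `n_core + 1` reactions.
#' @export
make_toy_chassis <- function(n_core = 5L, seed = 1L) {
  stopifnot(n_core >= 2)
  set.seed(seed)
  alphabet <- fixture_smiles_alphabet()
  smis <- sample(alphabet, n_core, replace = n_core > length(alphabet))
  core <- sprintf("C%d", seq_len(n_core))
  species <- c(
    list(species_record("EXT_b", name = "uptake boundary")),
    lapply(seq_len(n_core), function(i) fixture_species(core[i], smiles = smis[i])),
    list(species_record("BIOMASS_b", name = "biomass boundary"))
  )
  reactions <- c(
    list(reaction_record("R_uptake",
                         reactants = c(EXT_b = 1),
                         products = stats::setNames(1, core[1]),
                         lower_bound = 0, upper_bound = 10)),
    lapply(seq_len(n_core - 1), function(i) {
      reaction_record(sprintf("R_core%d", i),
                      reactants = stats::setNames(1, core[i]),
                      products = stats::setNames(1, core[i + 1]))
    }),
    list(reaction_record("R_biomass",
                         reactants = stats::setNames(1, core[n_core]),
                         products = c(BIOMASS_b = 1)))
  )
  chassis_model(
    id = sprintf("toy_chassis_%d_%d", n_core, seed),
    species = species, reactions = reactions,
    biomass_reaction_id = "R_biomass",
    taxon_id = 511145L,
    ignored_species = c("EXT_b", "BIOMASS_b")
  )
}

#' Generate a labeled pathway collection with planted structure
#'
#' Pathways attach to a random chassis core metabolite and run through fresh
#' intermediates to a synthetic target; roughly half the reactions carry a
#' cofactor pair. Exactly `round(n_pathways * positive_fraction)` pathways
#' are labeled positive and receive the planted effect: pathway Gibbs energy
#' shifted down by `effect_size` noise standard deviations, target flux and
#' enzyme-availability scores shifted up. With `effect_size = 0` the labels
#' are independent of every feature.
#'
#' @param n_pathways collection size.
#' @param chassis an `rp_chassis` (see [make_toy_chassis()]).
#' @param seed RNG seed.
#' @param n_reactions_range integer range of pathway lengths.
#' @param positive_fraction fraction of positives in (0, 1).
#' @param effect_size planted separation in noise-standard-deviation units.
#' @param cofactor_set character vector of cofactor species ids (structures
#'   assigned from the fixture alphabet).
#' @return list with `pathways` (list of `rp_pathway` with populated
#'   `pathway_dg` and `target_flux` properties) and `labels` (logical).
#' @export
make_pathway_set <- function(n_pathways, chassis, seed = 1L,
                             n_reactions_range = c(3L, 8L),
                             positive_fraction = 0.095,
                             effect_size = 3,
                             cofactor_set = c("CF_A", "CF_B")) {
  stopifnot(n_pathways >= 2, positive_fraction > 0, positive_fraction < 1,
            n_reactions_range[1] >= 1,
            n_reactions_range[1] <= n_reactions_range[2])
  set.seed(seed)
  alphabet <- fixture_smiles_alphabet()
  core_ids <- grep("^C[0-9]+$", names(chassis$species), value = TRUE)

  n_pos <- max(1L, round(n_pathways * positive_fraction))
  labels <- rep(FALSE, n_pathways)
  labels[sample(n_pathways, n_pos)] <- TRUE

  cof_species <- lapply(seq_along(cofactor_set), function(i) {
    fixture_species(cofactor_set[i], smiles = alphabet[(i - 1) %% 32 + 1])
  })
  names(cof_species) <- cofactor_set

  dg_sd <- 10; flux_sd <- 1
  pathways <- vector("list", n_pathways)
  for (i in seq_len(n_pathways)) {
    L <- sample(seq(n_reactions_range[1], n_reactions_range[2]), 1)
    substrate <- sample(core_ids, 1)
    target <- sprintf("TRG_%04d", i)
    inter <- if (L > 1) sprintf("X_%04d_%d", i, seq_len(L - 1)) else character()
    chain <- c(substrate, inter, target)
    species <- c(
      chassis$species[substrate],
      stats::setNames(lapply(c(inter, target), function(sid) {
        fixture_species(sid, smiles = sample(alphabet, 1))
      }), c(inter, target)),
      cof_species
    )
    pos <- labels[i]
    avail_shift <- if (pos) effect_size * 0.1 else 0
    reactions <- lapply(seq_len(L), function(j) {
      with_cof <- j %% 2 == 0 && length(cofactor_set) >= 2
      lhs <- stats::setNames(1, chain[j])
      rhs <- stats::setNames(1, chain[j + 1])
      if (with_cof) {
        lhs <- c(lhs, stats::setNames(1, cofactor_set[1]))
        rhs <- c(rhs, stats::setNames(1, cofactor_set[2]))
      }
      reaction_record(
        sprintf("RXN_%04d_%d", i, j),
        reactants = lhs, products = rhs,
        rule_id = sprintf("RR_%04d_%d", i, j),
        rule_score = min(1, max(0, stats::runif(1, 0.2, 0.8) + avail_shift)),
        dg_prime = stats::rnorm(1, -5, 3)
      )
    })
    dg <- stats::rnorm(1, -20, dg_sd) - (if (pos) effect_size * dg_sd else 0)
    flux <- max(0.05, stats::rnorm(1, 2, flux_sd) + (if (pos) effect_size * flux_sd else 0))
    used <- unique(unlist(lapply(reactions, function(r)
      c(names(r$reactants), names(r$products)))))
    pathways[[i]] <- pathway_record(
      id = sprintf("SYN_%04d", i),
      reactions = reactions,
      target_id = target,
      species = species[used],
      properties = list(pathway_dg = dg, target_flux = flux)
    )
  }
  list(pathways = pathways, labels = labels)
}

#' Generate a formation-energy table covering a pathway collection
#'
#' One row per distinct species id, keyed by id, making every reaction of
#' the given pathways fully resolvable unless a missingness fraction is
#' requested (in which case that fraction of species is dropped from the
#' table).
#'
#' @param pathways list of `rp_pathway` (or a single one).
#' @param seed RNG seed for energies and missingness.
#' @param missing_fraction fraction of species left out of the table.
#' @return data frame with `provider_key`, `dg_kj_mol`, `uncertainty`,
#'   suitable for [formation_provider()].
#' @export
make_formation_table <- function(pathways, seed = 1L, missing_fraction = 0) {
  if (inherits(pathways, "rp_pathway")) pathways <- list(pathways)
  set.seed(seed)
  ids <- sort(unique(unlist(lapply(pathways, function(p) names(p$species)))))
  df <- data.frame(
    provider_key = ids,
    dg_kj_mol = round(stats::rnorm(length(ids), -150, 80), 2),
    uncertainty = round(stats::runif(length(ids), 0.5, 5), 2),
    stringsAsFactors = FALSE)
  if (missing_fraction > 0) {
    drop <- sample(length(ids), floor(missing_fraction * length(ids)))
    if (length(drop)) df <- df[-drop, , drop = FALSE]
  }
  df
}

#' Generate a rule database with a matching master pathway
#'
#' Builds a linear master pathway of `n_rules` transformations
#' (`M0 -> M1 -> ... -> target`), transformation i referencing rule `RR_i`
#' which carries `templates_per_rule[i]` template reactions. Template j > 1
#' re-adds a cofactor pair, so completed alternatives differ by cofactors
#' and the enumeration count is exactly `prod(templates_per_rule)`.
#' With `share_template = TRUE` the first transformation references a second
#' rule whose only template duplicates the first rule's first template,
#' planting a duplicate that enumeration must collapse.
#'
#' @param n_rules number of transformations/rules (>= 1).
#' @param templates_per_rule integer scalar or vector (recycled).
#' @param seed RNG seed for rule scores.
#' @param share_template plant a duplicated template under a second rule id.
#' @return list with `db` (`rp_rule_db`), `master` (`rp_master_pathway`) and
#'   `species` (named list for structure-based deduplication).
#' @export
make_rule_db <- function(n_rules = 2L, templates_per_rule = 2L, seed = 1L,
                         share_template = FALSE) {
  stopifnot(n_rules >= 1)
  set.seed(seed)
  tpr <- rep_len(templates_per_rule, n_rules)
  alphabet <- fixture_smiles_alphabet()
  backbone <- sprintf("M%d", 0:n_rules)
  rows <- list()
  for (i in seq_len(n_rules)) {
    for (j in seq_len(tpr[i])) {
      cof <- if (j > 1) sprintf(" + 1 CFA_%d", j - 1) else ""
      cofp <- if (j > 1) sprintf(" + 1 CFB_%d", j - 1) else ""
      rows[[length(rows) + 1L]] <- data.frame(
        rule_id = sprintf("RR_%d", i),
        template_id = sprintf("TPL_%d_%d", i, j),
        equation = sprintf("1 %s%s <=> 1 %s%s", backbone[i], cof,
                           backbone[i + 1], cofp),
        direction = "forward",
        rule_score = round(stats::runif(1, 0.3, 0.95), 3),
        stringsAsFactors = FALSE)
    }
  }
  if (share_template) {
    first <- rows[[1]]
    rows[[length(rows) + 1L]] <- data.frame(
      rule_id = "RR_1_alt", template_id = first$template_id,
      equation = first$equation, direction = "forward",
      rule_score = first$rule_score, stringsAsFactors = FALSE)
  }
  db <- read_rule_db(do.call(rbind, rows))

  transformations <- lapply(seq_len(n_rules), function(i) {
    rule_ids <- sprintf("RR_%d", i)
    if (share_template && i == 1) rule_ids <- c(rule_ids, "RR_1_alt")
    transformation(sprintf("T%d", i),
                   lhs = stats::setNames(1, backbone[i]),
                   rhs = stats::setNames(1, backbone[i + 1]),
                   rule_ids = rule_ids)
  })
  master <- master_pathway(sprintf("MP_%d", seed), transformations,
                           target_id = backbone[n_rules + 1])

  sp_ids <- c(backbone,
              sprintf("CFA_%d", seq_len(max(0, max(tpr) - 1))),
              sprintf("CFB_%d", seq_len(max(0, max(tpr) - 1))))
  species <- stats::setNames(lapply(seq_along(sp_ids), function(k) {
    fixture_species(sp_ids[k], smiles = alphabet[(k - 1) %% 32 + 1])
  }), sp_ids)
  list(db = db, master = master, species = species)
}
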
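## Expansion of "master" pathways (rule-level chemical transformations) into
## complete reaction pathways: one fork per reaction rule referenced by a
## transformation, then one fork per template reaction behind each rule, with
## cofactors re-added from the template and duplicate pathways removed.

#' Rule-level chemical transformation
#'
#' A cofactor-free transformation as produced by retrosynthesis, referencing
#' one or more reaction rules.
#'
#' @param id identifier.
#' @param lhs,rhs named numeric vectors (species id to positive stoichiometry).
#' @param rule_ids non-empty character vector of rule identifiers.
#' @return an object of class `rp_transformation`.
#' @export
transformation <- function(id, lhs, rhs, rule_ids) {
  if (!length(rule_ids)) stop(sprintf("transformation '%s': rule_ids must be non-empty", id))
  structure(list(id = id, lhs = lhs, rhs = rhs, rule_ids = rule_ids),
            class = "rp_transformation")
}

#' Master pathway
#'
#' An ordered list of transformations leading to a target species, prior to
#' cofactor completion.
#'
#' @param id identifier.
#' @param transformations non-empty list of [transformation()] objects.
#' @param target_id target species id.
#' @return an object of class `rp_master_pathway`.
#' @export
master_pathway <- function(id, transformations, target_id) {
  if (!length(transformations)) stop("master pathway needs at least one transformation")
  names(transformations) <- vapply(transformations, `[[`, character(1), "id")
  structure(list(id = id, transformations = transformations,
                 target_id = target_id),
            class = "rp_master_pathway")
}

#' Parse a reaction equation
#'
#' Grammar: `n id + n id + ... <=> n id + ...`, with optional leading
#' coefficients (default 1).
#'
#' @param eq equation string.
#' @return list with named numeric vectors `lhs` and `rhs`.
#' @export
parse_equation <- function(eq) {
  sides <- strsplit(eq, "<=>", fixed = TRUE)[[1]]
  if (length(sides) != 2) stop(sprintf("malformed equation (need one '<=>'): %s", eq))
  parse_side_eq <- function(s) {
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    terms <- terms[nzchar(terms)]
    out <- numeric(0)
    for (tm in terms) {
      parts <- strsplit(tm, "\\s+")[[1]]
      if (length(parts) == 2 && !is.na(suppressWarnings(as.numeric(parts[1])))) {
        out[parts[2]] <- as.numeric(parts[1])
      } else if (length(parts) == 1) {
        out[parts[1]] <- 1
      } else {
        stop(sprintf("malformed equation term: '%s'", tm))
      }
    }
    out
  }
  list(lhs = parse_side_eq(sides[1]), rhs = parse_side_eq(sides[2]))
}

#' Read a rule database from TSV
#'
#' Five tab-separated columns: `rule_id`, `template_id`, `equation`
#' (see [parse_equation()]), `direction` (`forward` or `reverse`; reverse
#' templates are flipped on load), `rule_score` in \[0, 1\].
#'
#' @param path TSV file path, or a data frame with those columns.
#' @return an object of class `rp_rule_db`: a named list mapping rule id to a
#'   list of template entries (`template_id`, `lhs`, `rhs`, `rule_score`).
#' @export
read_rule_db <- function(path) {
  df <- if (is.data.frame(path)) path else {
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
  needed <- c("rule_id", "template_id", "equation", "direction", "rule_score")
  if (!all(needed %in% names(df))) {
    stop("rule database needs columns: ", paste(needed, collapse = ", "))
  }
  if (any(df$rule_score < 0 | df$rule_score > 1)) {
    stop("rule_score values must lie in [0, 1]")
  }
  entries <- list()
  for (i in seq_len(nrow(df))) {
    eq <- parse_equation(df$equation[i])
    if (identical(df$direction[i], "reverse")) eq <- list(lhs = eq$rhs, rhs = eq$lhs)
    entry <- list(template_id = df$template_id[i], lhs = eq$lhs, rhs = eq$rhs,
                  rule_score = df$rule_score[i])
    rid <- df$rule_id[i]
    entries[[rid]] <- c(entries[[rid]], list(entry))
  }
  structure(entries, class = "rp_rule_db")
}

#' Write a rule database to TSV
#'
#' @param db an `rp_rule_db`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rule_db <- function(db, path) {
  fmt_side <- function(v) paste(sprintf("%s %s", format_stoich(unname(v)), names(v)),
                                collapse = " + ")
  rows <- list()
  for (rid in names(db)) {
    for (e in db[[rid]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        rule_id = rid, template_id = e$template_id,
        equation = paste(fmt_side(e$lhs), "<=>", fmt_side(e$rhs)),
        direction = "forward", rule_score = e$rule_score,
        stringsAsFactors = FALSE)
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Complete a transformation against a rule database
#'
#' For every (rule, template) pair referenced by the transformation, builds
#' one full reaction: the transformation's own left/right species plus the
#' template's cofactors (template species absent from the rule-level
#' transformation), annotated with rule id, template id and rule score.
#' Template equations are expected to share the species namespace of the
#' transformations.
#'
#' @param t an [transformation()].
#' @param db an `rp_rule_db`.
#' @return list of `rp_reaction` objects, one per (rule, template) pair, in
#'   rule-then-template order.
#' @export
complete_transformation <- function(t, db) {
  missing_rules <- setdiff(t$rule_ids, names(db))
  if (length(missing_rules)) {
    stop(sprintf("transformation '%s': unknown rule id(s): %s",
                 t$id, paste(missing_rules, collapse = ", ")))
  }
  out <- list()
  main <- c(names(t$lhs), names(t$rhs))
  for (rid in t$rule_ids) {
    for (e in db[[rid]]) {
      co_l <- e$lhs[setdiff(names(e$lhs), main)]
      co_r <- e$rhs[setdiff(names(e$rhs), main)]
      add <- function(a, b) {
        v <- c(a, b)
        tapply_sum <- tapply(v, names(v), sum)
        stats::setNames(as.numeric(tapply_sum), names(tapply_sum))
      }
      out[[length(out) + 1L]] <- reaction_record(
        id = paste(t$id, rid, e$template_id, sep = "__"),
        reactants = add(t$lhs, co_l),
        products = add(t$rhs, co_r),
        rule_id = rid, template_id = e$template_id,
        rule_score = e$rule_score
      )
    }
  }
  out
}

#' Enumerate complete pathways from a master pathway
#'
#' Takes the Cartesian product of the per-transformation completed-reaction
#' alternatives, removes duplicate pathways (identical multisets of completed
#' reactions under structure-based species identity: InChIKey when present,
#' else species id, with stoichiometries compared to 1e-9), and returns the
#' survivors in lexicographic order of their reaction-id tuples.
#'
#' An optional cut keeps only the `keep_top` best pathways, ranked by
#' descending mean rule score with ties broken lexicographically by pathway
#' id.
#'
#' @param m a [master_pathway()].
#' @param db an `rp_rule_db`.
#' @param species optional named list of [species_record()] used for
#'   structure-based duplicate detection; species missing from it are
#'   compared by id.
#' @param keep_top optional integer: keep only the best N pathways.
#' @return list of `rp_pathway` objects.
#' @export
enumerate_pathways <- function(m, db, species = NULL, keep_top = NULL) {
  alts <- lapply(m$transformations, complete_transformation, db = db)
  combos <- expand.grid(lapply(alts, seq_along), KEEP.OUT.ATTRS = FALSE)

  species <- species %||% list()
  ensure_species <- function(ids) {
    for (sid in ids) {
      if (is.null(species[[sid]])) species[[sid]] <<- species_record(sid)
    }
  }
  pathways <- list()
  seen <- character()
  for (i in seq_len(nrow(combos))) {
    rxns <- lapply(seq_along(alts), function(j) alts[[j]][[combos[i, j]]])
    ensure_species(unique(unlist(lapply(rxns, function(r)
      c(names(r$reactants), names(r$products))))))
    sigs <- sort(vapply(rxns, reaction_signature, character(1), species = species))
    key <- paste(sigs, collapse = " || ")
    if (key %in% seen) next
    seen <- c(seen, key)
    refd <- unique(unlist(lapply(rxns, function(r)
      c(names(r$reactants), names(r$products)))))
    pathways[[length(pathways) + 1L]] <- pathway_record(
      id = sprintf("%s_%03d", m$id, i),
      reactions = rxns,
      target_id = m$target_id,
      species = species[refd]
    )
  }
  ## deterministic order: lexicographic by reaction-id tuple
  tuples <- vapply(pathways, function(p) paste(names(p$reactions), collapse = "|"),
                   character(1))
  pathways <- pathways[order(tuples)]
  for (i in seq_along(pathways)) {
    pathways[[i]]$id <- sprintf("%s_%03d", m$id, i)
  }
  if (!is.null(keep_top) && length(pathways) > keep_top) {
    mean_score <- vapply(pathways, function(p) {
      mean(vapply(p$reactions, function(r) r$rule_score %||% 0, numeric(1)))
    }, numeric(1))
    ids <- vapply(pathways, `[[`, character(1), "id")
    pathways <- pathways[order(-mean_score, ids)][seq_len(keep_top)]
  }
  pathways
}
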
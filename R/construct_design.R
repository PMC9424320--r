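## Combinatorial BASIC-style construct design: one constitutive promoter, an
## ordered operon of (CDS, RBS-linker) slots, one backbone. With G genes, P
## promoters and R linker variants assignable per gene, enabling gene-order
## permutation yields P * R^G * G! designs.

#' Parts registry
#'
#' @param promoters,rbs_linkers,cds non-empty character vectors of unique
#'   part ids.
#' @param backbone single backbone part id.
#' @return an object of class `rp_parts_registry`.
#' @export
parts_registry <- function(promoters, rbs_linkers, cds, backbone) {
  for (nm in c("promoters", "rbs_linkers", "cds")) {
    v <- get(nm)
    if (!length(v)) stop(sprintf("registry field '%s' is empty", nm))
    if (anyDuplicated(v)) stop(sprintf("registry field '%s' has duplicate ids", nm))
  }
  if (length(backbone) != 1 || !nzchar(backbone)) stop("registry needs one backbone id")
  structure(list(promoters = promoters, rbs_linkers = rbs_linkers,
                 cds = cds, backbone = backbone),
            class = "rp_parts_registry")
}

#' Read a parts registry from CSV
#'
#' Columns `part_id` and `type` (`promoter`, `rbs_linker`, `cds`,
#' `backbone`).
#'
#' @param path CSV file path or data frame.
#' @return an `rp_parts_registry`.
#' @export
read_parts_registry <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  pick <- function(ty) df$part_id[df$type == ty]
  parts_registry(
    promoters = pick("promoter"),
    rbs_linkers = pick("rbs_linker"),
    cds = pick("cds"),
    backbone = pick("backbone")
  )
}

permutations_of <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations_of(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}

#' Enumerate combinatorial construct designs
#'
#' Full factorial enumeration over promoters, per-slot RBS-linker
#' assignments and (optionally) CDS orderings:
#' `|promoters| * |rbs_linkers|^G * G!` designs with permutation enabled,
#' `|promoters| * |rbs_linkers|^G` with the given gene order only. Output is
#' sorted lexicographically by (promoter, slot parts) and design ids are a
#' deterministic function of the design content, so repeated runs are
#' byte-stable.
#'
#' @param reg an `rp_parts_registry`.
#' @param permute enumerate all CDS orderings (default `TRUE`).
#' @param exclude optional character vector of design ids to drop (e.g.
#'   designs a downstream assembly protocol cannot build).
#' @return list of `rp_construct` objects, each with `promoter`, `slots`
#'   (data frame of `cds`, `rbs_linker` in operon order), `backbone` and
#'   `design_id`.
#' @export
enumerate_constructs <- function(reg, permute = TRUE, exclude = character()) {
  stopifnot(inherits(reg, "rp_parts_registry"))
  g <- length(reg$cds)
  orders <- if (permute) permutations_of(sort(reg$cds)) else list(reg$cds)
  linker_grid <- expand.grid(rep(list(sort(reg$rbs_linkers)), g),
                             KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  designs <- list()
  for (prom in sort(reg$promoters)) {
    for (ord in orders) {
      for (i in seq_len(nrow(linker_grid))) {
        linkers <- as.character(linker_grid[i, ])
        slots <- data.frame(cds = ord, rbs_linker = linkers,
                            stringsAsFactors = FALSE)
        design_id <- paste(
          c(reg$backbone, prom, as.vector(rbind(linkers, ord))),
          collapse = "_")
        designs[[length(designs) + 1L]] <- structure(
          list(promoter = prom, slots = slots, backbone = reg$backbone,
               design_id = design_id),
          class = "rp_construct")
      }
    }
  }
  keys <- vapply(designs, `[[`, character(1), "design_id")
  designs <- designs[order(keys)]
  if (length(exclude)) {
    designs <- Filter(function(d) !(d$design_id %in% exclude), designs)
  }
  designs
}

#' Write an assembly plan CSV
#'
#' One row per design: `design_id`, `backbone`, `promoter`, then
#' `slot<i>_linker`, `slot<i>_cds` pairs in operon order. Round-trips
#' through [read_assembly_plan()].
#'
#' @param designs non-empty list of `rp_construct` sharing one slot count.
#' @param path output file path, or `NULL` to return the CSV text.
#' @return the CSV text (invisibly when `path` is given).
#' @export
write_assembly_plan <- function(designs, path = NULL) {
  if (!length(designs)) stop("no designs to write")
  ids <- vapply(designs, `[[`, character(1), "design_id")
  if (anyDuplicated(ids)) {
    stop("duplicate design ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  g <- nrow(designs[[1]]$slots)
  header <- c("design_id", "backbone", "promoter",
              as.vector(rbind(sprintf("slot%d_linker", seq_len(g)),
                              sprintf("slot%d_cds", seq_len(g)))))
  rows <- vapply(designs, function(d) {
    stopifnot(nrow(d$slots) == g)
    paste(c(d$design_id, d$backbone, d$promoter,
            as.vector(rbind(d$slots$rbs_linker, d$slots$cds))),
          collapse = ",")
  }, character(1))
  txt <- paste0(paste(c(paste(header, collapse = ","), rows), collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(txt)
}

#' Read an assembly plan CSV
#'
#' @param path file path or CSV text.
#' @return list of `rp_construct` objects.
#' @export
read_assembly_plan <- function(path) {
  is_path <- length(path) == 1 && !grepl("\n", path, fixed = TRUE) &&
    file.exists(path)
  df <- if (is_path) utils::read.csv(path, stringsAsFactors = FALSE)
        else utils::read.csv(text = path, stringsAsFactors = FALSE)
  linker_cols <- grep("^slot[0-9]+_linker$", names(df), value = TRUE)
  g <- length(linker_cols)
  lapply(seq_len(nrow(df)), function(i) {
    structure(
      list(promoter = df$promoter[i],
           slots = data.frame(
             cds = as.character(df[i, sprintf("slot%d_cds", seq_len(g))]),
             rbs_linker = as.character(df[i, sprintf("slot%d_linker", seq_len(g))]),
             stringsAsFactors = FALSE),
           backbone = df$backbone[i],
           design_id = df$design_id[i]),
      class = "rp_construct")
  })
}
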
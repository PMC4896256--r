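#' Construct a genome-scale metabolic model
#'
#' A constraint-based model holds the stoichiometric matrix \eqn{A}
#' (\eqn{m} metabolites by \eqn{n} reactions), default flux bounds
#' \eqn{V^{min}, V^{max}} (mmol h\eqn{^{-1}} gDW\eqn{^{-1}}), and an
#' optional GPR rule per reaction. Steady-state flux vectors \eqn{v}
#' satisfy \eqn{Av = 0} with \eqn{V^{min} \le v \le V^{max}}.
#'
#' @param S stoichiometric matrix, metabolites as rows, reactions as
#'   columns. Dimnames are used as ids when `metabolite_ids`/`reaction_ids`
#'   are not given.
#' @param lower_bounds,upper_bounds numeric vectors of length `ncol(S)`.
#' @param gpr named list (by reaction id) of `gpr` trees or GPR strings;
#'   reactions absent from the list carry no gene association.
#' @param metabolite_ids,reaction_ids,gene_ids identifier vectors; `gene_ids`
#'   defaults to the union of genes referenced by the GPRs.
#' @return an object of class `metabolic_model` with fields `S`,
#'   `lower_bounds`, `upper_bounds`, `gpr`, `metabolite_ids`,
#'   `reaction_ids`, `gene_ids`.
#' @examples
#' m <- metabolic_model(
#'   S = matrix(c(1, -1, -1), 1, dimnames = list("M", c("uptake", "biomass", "product"))),
#'   lower_bounds = c(0, 0, 0), upper_bounds = c(10, 1000, 1000),
#'   gpr = list(uptake = "gU")
#' )
#' m
#' @export
metabolic_model <- function(S, lower_bounds, upper_bounds, gpr = list(),
                            metabolite_ids = rownames(S),
                            reaction_ids = colnames(S),
                            gene_ids = NULL) {
  S <- as.matrix(S)
  if (is.null(metabolite_ids) || is.null(reaction_ids))
    stop("metabolite and reaction ids are required (dimnames of S or explicit)", call. = FALSE)
  gpr <- lapply(gpr, function(g) if (inherits(g, "gpr")) g else parse_gpr(g))
  if (is.null(gene_ids))
    gene_ids <- unique(unlist(lapply(gpr, gpr_genes), use.names = FALSE))
  if (is.null(gene_ids)) gene_ids <- character(0)
  dimnames(S) <- list(metabolite_ids, reaction_ids)
  model <- structure(
    list(S = S,
         lower_bounds = stats::setNames(as.numeric(lower_bounds), reaction_ids),
         upper_bounds = stats::setNames(as.numeric(upper_bounds), reaction_ids),
         gpr = gpr,
         metabolite_ids = as.character(metabolite_ids),
         reaction_ids = as.character(reaction_ids),
         gene_ids = as.character(gene_ids)),
    class = "metabolic_model")
  validate_model(model)
  model
}

#' Validate a metabolic model's invariants
#'
#' Checks dimension consistency, id uniqueness, bound ordering
#' (`lower_bounds <= upper_bounds`) and that every gene referenced by a GPR
#' appears in `gene_ids`. Called by the constructor; exported so readers and
#' augmentation can re-check.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; errors describe the first violated invariant.
#' @export
validate_model <- function(model) {
  m <- length(model$metabolite_ids); n <- length(model$reaction_ids)
  if (!all(dim(model$S) == c(m, n)))
    stop("stoichiometric matrix dimensions do not match id lists", call. = FALSE)
  if (anyDuplicated(model$metabolite_ids))
    stop("duplicate metabolite ids: ",
         paste(unique(model$metabolite_ids[duplicated(model$metabolite_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(model$reaction_ids))
    stop("duplicate reaction ids: ",
         paste(unique(model$reaction_ids[duplicated(model$reaction_ids)]), collapse = ", "),
         call. = FALSE)
  if (length(model$lower_bounds) != n || length(model$upper_bounds) != n)
    stop("bound vectors must have one entry per reaction", call. = FALSE)
  bad <- which(model$lower_bounds > model$upper_bounds)
  if (length(bad))
    stop("lower bound exceeds upper bound for reaction(s): ",
         paste(model$reaction_ids[bad], collapse = ", "), call. = FALSE)
  if (length(model$gpr)) {
    if (is.null(names(model$gpr)) || !all(names(model$gpr) %in% model$reaction_ids))
      stop("gpr list must be named by known reaction ids", call. = FALSE)
    used <- unique(unlist(lapply(model$gpr, gpr_genes), use.names = FALSE))
    missing <- setdiff(used, model$gene_ids)
    if (length(missing))
      stop("genes referenced by GPRs but absent from gene_ids: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %d metabolites x %d reactions, %d genes, %d GPR rules\n",
              length(x$metabolite_ids), length(x$reaction_ids),
              length(x$gene_ids), length(x$gpr)))
  invisible(x)
}

#' Read a metabolic model from SBML or the package JSON dialect
#'
#' The JSON dialect (written by [write_model()]) is:
#' \preformatted{
#' {"metabolites": [{"id": "M"}, ...],
#'  "reactions": [{"id": "uptake",
#'                 "stoichiometry": {"M": 1.0},
#'                 "lower_bound": 0, "upper_bound": 10,
#'                 "gpr": "gU"}, ...],
#'  "genes": ["gU", ...]}
#' }
#' SBML input must be Level 3 with the `fbc` package for flux bounds and
#' gene associations. Reactions without explicit bounds default to
#' `(-default_bound, default_bound)` when reversible and
#' `(0, default_bound)` otherwise.
#'
#' @param path file path.
#' @param format `"json"` or `"sbml"`; guessed from the file extension by default.
#' @param default_bound bound magnitude used when a file omits bounds
#'   (mmol h\eqn{^{-1}} gDW\eqn{^{-1}}).
#' @return a `metabolic_model`.
#' @export
read_model <- function(path, format = c("auto", "json", "sbml"), default_bound = 1000) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  switch(format,
         json = read_model_json(path, default_bound),
         sbml = read_model_sbml(path, default_bound))
}

read_model_json <- function(path, default_bound = 1000) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("JSON parse failure in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  for (field in c("metabolites", "reactions"))
    if (is.null(doc[[field]]))
      stop("JSON model missing required element '", field, "'", call. = FALSE)
  met_ids <- vapply(doc$metabolites, function(x) as.character(x$id), character(1))
  rxn_ids <- vapply(doc$reactions, function(x) as.character(x$id), character(1))
  S <- matrix(0, length(met_ids), length(rxn_ids), dimnames = list(met_ids, rxn_ids))
  lb <- ub <- numeric(length(rxn_ids))
  gpr <- list()
  for (j in seq_along(doc$reactions)) {
    r <- doc$reactions[[j]]
    st <- r$stoichiometry
    if (is.null(st) || !length(st))
      stop("reaction '", rxn_ids[j], "' has empty stoichiometry", call. = FALSE)
    unknown <- setdiff(names(st), met_ids)
    if (length(unknown))
      stop("reaction '", rxn_ids[j], "' references unknown metabolite(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    S[names(st), j] <- vapply(st, as.numeric, numeric(1))
    rev_default <- isTRUE(r$reversible)
    lb[j] <- if (!is.null(r$lower_bound)) as.numeric(r$lower_bound) else
      if (rev_default) -default_bound else 0
    ub[j] <- if (!is.null(r$upper_bound)) as.numeric(r$upper_bound) else default_bound
    if (!is.null(r$gpr) && nzchar(r$gpr)) gpr[[rxn_ids[j]]] <- parse_gpr(r$gpr)
  }
  genes <- if (!is.null(doc$genes)) vapply(doc$genes, as.character, character(1)) else NULL
  metabolic_model(S, lb, ub, gpr, met_ids, rxn_ids, gene_ids = genes)
}

read_model_sbml <- function(path, default_bound = 1000) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  species <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  if (!length(species))
    stop("SBML format error: no <species> elements found (element listOfSpecies)", call. = FALSE)
  met_ids <- xml2::xml_attr(species, "id")
  boundary <- xml2::xml_attr(species, "boundaryCondition") %in% "true"
  met_ids <- met_ids[!boundary]

  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  gps <- xml2::xml_find_all(doc, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gp_label <- stats::setNames(xml2::xml_attr(gps, "label"), xml2::xml_attr(gps, "id"))
  gp_label[is.na(gp_label)] <- names(gp_label)[is.na(gp_label)]

  rxns <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rxns))
    stop("SBML format error: no <reaction> elements found (element listOfReactions)", call. = FALSE)
  rxn_ids <- xml2::xml_attr(rxns, "id")
  S <- matrix(0, length(met_ids), length(rxn_ids), dimnames = list(met_ids, rxn_ids))
  lb <- ub <- numeric(length(rxn_ids))
  gpr <- list()
  for (j in seq_along(rxns)) {
    rx <- rxns[[j]]
    for (side in c(-1, 1)) {
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      refs <- xml2::xml_find_all(rx, sprintf("./s:%s/s:speciesReference", tag), ns)
      for (ref in refs) {
        sp <- xml2::xml_attr(ref, "species")
        coef <- xml2::xml_attr(ref, "stoichiometry")
        coef <- if (is.na(coef)) 1 else as.numeric(coef)
        if (sp %in% met_ids) S[sp, j] <- S[sp, j] + side * coef
      }
    }
    reversible <- xml2::xml_attr(rx, "reversible") %in% "true"
    lb_ref <- xml2::xml_attr(rx, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(rx, "upperFluxBound")
    lb[j] <- if (!is.na(lb_ref) && lb_ref %in% names(pval)) pval[[lb_ref]] else
      if (reversible) -default_bound else 0
    ub[j] <- if (!is.na(ub_ref) && ub_ref %in% names(pval)) pval[[ub_ref]] else default_bound
    ga <- xml2::xml_find_first(rx, "./fbc:geneProductAssociation", ns)
    if (!inherits(ga, "xml_missing")) {
      root <- xml2::xml_find_first(ga, "./*")
      if (!inherits(root, "xml_missing"))
        gpr[[rxn_ids[j]]] <- sbml_gpr_tree(root, gp_label, ns)
    }
  }
  metabolic_model(S, lb, ub, gpr, met_ids, rxn_ids)
}

sbml_gpr_tree <- function(node, gp_label, ns) {
  tree <- sbml_gpr_walk(node, gp_label)
  class(tree) <- "gpr"
  tree
}

sbml_gpr_walk <- function(node, gp_label) {
  name <- xml2::xml_name(node)
  if (name == "geneProductRef") {
    gid <- xml2::xml_attr(node, "geneProduct")
    lbl <- if (gid %in% names(gp_label)) gp_label[[gid]] else gid
    return(list(gene = lbl))
  }
  if (name %in% c("and", "or")) {
    kids <- lapply(xml2::xml_children(node), sbml_gpr_walk, gp_label = gp_label)
    return(list(op = name, args = kids))
  }
  stop("SBML format error: unsupported gene-association element <", name, ">", call. = FALSE)
}

#' Write a metabolic model to the JSON dialect
#'
#' Field-for-field inverse of [read_model()] with `format = "json"`.
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  rxns <- lapply(seq_along(model$reaction_ids), function(j) {
    col <- stats::setNames(model$S[, j], model$metabolite_ids)
    st <- as.list(col[col != 0])
    r <- list(id = model$reaction_ids[j],
              stoichiometry = st,
              lower_bound = unname(model$lower_bounds[j]),
              upper_bound = unname(model$upper_bounds[j]))
    g <- model$gpr[[model$reaction_ids[j]]]
    if (!is.null(g)) r$gpr <- format_gpr(g)
    r
  })
  doc <- list(metabolites = lapply(model$metabolite_ids, function(id) list(id = id)),
              reactions = rxns,
              genes = as.list(model$gene_ids))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Augment a model with new reactions and updated GPR rules
#'
#' Generic model-augmentation operation: appends reactions (new metabolites
#' become new rows of \eqn{A}) and replaces listed GPR rules, leaving all
#' other content untouched. Typical use is merging an underground-reaction
#' catalogue and isozyme-derived GPR updates into a curated reconstruction.
#' Re-applying the same tables is a no-op: an addition whose reaction already
#' exists with identical content is skipped, while a conflicting duplicate is
#' an error.
#'
#' @param model a `metabolic_model`.
#' @param additions `NULL`, or a data.frame with columns `reaction_id`,
#'   `stoichiometry` (string `"met:coef, met:coef"`), `lower_bound`,
#'   `upper_bound` and optional `gpr` — see [read_reaction_additions()].
#' @param gpr_updates `NULL`, or a data.frame with columns `reaction_id` and
#'   `new_gpr` (optionally `old_gpr`, kept for provenance) — see
#'   [read_gpr_updates()].
#' @return the augmented `metabolic_model`.
#' @examples
#' m <- toy_model("chain")
#' upd <- data.frame(reaction_id = "uptake", new_gpr = "gU OR gU2")
#' m2 <- augment_model(m, gpr_updates = upd)
#' format_gpr(m2$gpr$uptake)
#' @export
augment_model <- function(model, additions = NULL, gpr_updates = NULL) {
  if (!is.null(additions) && nrow(additions)) {
    for (i in seq_len(nrow(additions))) {
      row <- additions[i, ]
      rid <- as.character(row$reaction_id)
      st <- parse_stoichiometry(row$stoichiometry)
      if (any(!is.finite(st)) || any(st == 0))
        stop("addition '", rid, "' has non-finite or zero coefficients", call. = FALSE)
      g_txt <- if (!is.null(row$gpr) && !is.na(row$gpr) && nzchar(row$gpr)) row$gpr else NULL
      if (rid %in% model$reaction_ids) {
        if (addition_matches(model, rid, st, row$lower_bound, row$upper_bound, g_txt)) next
        stop("duplicate addition: reaction '", rid,
             "' already exists with different content", call. = FALSE)
      }
      new_mets <- setdiff(names(st), model$metabolite_ids)
      S <- model$S
      if (length(new_mets)) {
        S <- rbind(S, matrix(0, length(new_mets), ncol(S),
                             dimnames = list(new_mets, colnames(S))))
      }
      newcol <- stats::setNames(numeric(nrow(S)), rownames(S))
      newcol[names(st)] <- st
      S <- cbind(S, newcol)
      colnames(S)[ncol(S)] <- rid
      gpr <- model$gpr
      if (!is.null(g_txt)) gpr[[rid]] <- parse_gpr(g_txt)
      model <- metabolic_model(
        S,
        c(model$lower_bounds, as.numeric(row$lower_bound)),
        c(model$upper_bounds, as.numeric(row$upper_bound)),
        gpr,
        rownames(S), colnames(S),
        gene_ids = union(model$gene_ids,
                         if (is.null(g_txt)) character(0) else gpr_genes(gpr[[rid]])))
    }
  }
  if (!is.null(gpr_updates) && nrow(gpr_updates)) {
    unknown <- setdiff(as.character(gpr_updates$reaction_id), model$reaction_ids)
    if (length(unknown))
      stop("GPR update references unknown reaction(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    for (i in seq_len(nrow(gpr_updates))) {
      rid <- as.character(gpr_updates$reaction_id[i])
      tree <- parse_gpr(as.character(gpr_updates$new_gpr[i]))
      model$gpr[[rid]] <- tree
      model$gene_ids <- union(model$gene_ids, gpr_genes(tree))
    }
    validate_model(model)
  }
  model
}

parse_stoichiometry <- function(text) {
  if (is.list(text)) text <- text[[1]]
  if (is.numeric(text)) return(text)  # already a named vector
  parts <- strsplit(trimws(as.character(text)), "[,;]")[[1]]
  parts <- parts[nzchar(trimws(parts))]
  kv <- strsplit(parts, ":", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad))
    stop("malformed stoichiometry term: ", paste(parts[bad], collapse = ", "), call. = FALSE)
  stats::setNames(vapply(kv, function(x) as.numeric(x[2]), numeric(1)),
                  vapply(kv, function(x) trimws(x[1]), character(1)))
}

addition_matches <- function(model, rid, st, lb, ub, g_txt) {
  col <- stats::setNames(model$S[, rid], model$metabolite_ids)
  cur <- col[col != 0]
  same_st <- length(cur) == length(st) && all(names(st) %in% names(cur)) &&
    isTRUE(all.equal(unname(cur[names(st)]), unname(st)))
  same_bounds <- isTRUE(all.equal(unname(model$lower_bounds[rid]), as.numeric(lb))) &&
    isTRUE(all.equal(unname(model$upper_bounds[rid]), as.numeric(ub)))
  cur_g <- model$gpr[[rid]]
  same_g <- (is.null(cur_g) && is.null(g_txt)) ||
    (!is.null(cur_g) && !is.null(g_txt) &&
       identical(format_gpr(cur_g), format_gpr(parse_gpr(g_txt))))
  same_st && same_bounds && same_g
}

#' Read a reaction-addition table
#'
#' Tab-separated text with a header and columns `reaction_id`,
#' `stoichiometry` (string `"met:coef, met:coef"`; negative = consumed),
#' `lower_bound`, `upper_bound`, and optional `gpr`.
#'
#' @param path file path.
#' @return a data.frame suitable for [augment_model()].
#' @export
read_reaction_additions <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("reaction_id", "stoichiometry", "lower_bound", "upper_bound")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("addition table missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  tab
}

#' Read a GPR-update table
#'
#' Tab-separated text with a header and columns `reaction_id`, `new_gpr`,
#' and optional `old_gpr` (documentation of the rule being replaced; not
#' enforced, so updates stay idempotent).
#'
#' @param path file path.
#' @return a data.frame suitable for [augment_model()].
#' @export
read_gpr_updates <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(c("reaction_id", "new_gpr"), names(tab))
  if (length(missing))
    stop("GPR update table missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  for (g in tab$new_gpr) parse_gpr(g)  # fail fast on malformed rules
  tab
}
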
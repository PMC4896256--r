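# Bounded LP: optimize obj'v subject to S v = 0, lb <= v <= ub, and optional
# extra rows a'v >= rhs. Variables are shifted by lb so the simplex works on
# x = v - lb >= 0.
solve_lp <- function(obj, S, lb, ub, extra_ge = NULL, maximize = TRUE) {
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("LP requires finite bounds", call. = FALSE)
  n <- length(lb)
  Age <- NULL; bge <- NULL
  if (!is.null(extra_ge)) {
    Age <- do.call(rbind, lapply(extra_ge, function(row) row$a))
    bge <- vapply(extra_ge, function(row) row$rhs - sum(row$a * lb), numeric(1))
  }
  res <- dense_simplex(obj,
                       Aeq = as.matrix(S), beq = as.numeric(-S %*% lb),
                       Ale = diag(n), ble = ub - lb,
                       Age = Age, bge = bge,
                       maximize = maximize)
  if (res$status != "optimal")
    return(list(status = res$status, v = rep(NA_real_, n), objective = NA_real_))
  v <- res$x + lb
  list(status = "optimal", v = v, objective = sum(obj * v))
}

#' Build a 0/1 objective selector over reactions
#'
#' @param model a `metabolic_model`.
#' @param reactions character vector of reaction ids to select (weight 1).
#' @return named numeric vector of length `n` with ones at the selected
#'   reactions.
#' @export
objective_selector <- function(model, reactions) {
  unknown <- setdiff(reactions, model$reaction_ids)
  if (length(unknown))
    stop("objective references unknown reaction(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  sel <- stats::setNames(numeric(length(model$reaction_ids)), model$reaction_ids)
  sel[reactions] <- 1
  sel
}

as_selector <- function(model, objective) {
  if (is.character(objective)) return(objective_selector(model, objective))
  if (length(objective) != length(model$reaction_ids))
    stop("objective selector length does not match reaction count", call. = FALSE)
  if (all(objective == 0)) stop("objective selector is all zero", call. = FALSE)
  stats::setNames(as.numeric(objective), model$reaction_ids)
}

new_flux_distribution <- function(model, v, objective_values, status,
                                  feas_tol = 1e-6) {
  fluxes <- stats::setNames(v, model$reaction_ids)
  if (status == "optimal") {
    resid <- max(abs(model$S %*% v))
    if (resid > feas_tol)
      stop(sprintf("steady-state residual %.3g exceeds tolerance %g", resid, feas_tol),
           call. = FALSE)
  }
  structure(list(fluxes = fluxes, objective_values = objective_values,
                 status = status),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat(sprintf("<flux_distribution> status: %s; objective(s): %s\n", x$status,
              paste(signif(x$objective_values, 6), collapse = ", ")))
  invisible(x)
}

#' Flux-balance analysis
#'
#' Maximizes a linear objective over the steady-state flux polytope
#' \eqn{\{v : Av = 0,\ V^{min} \le v \le V^{max}\}}.
#'
#' @param model a `metabolic_model` (typically after [condition_bounds()]).
#' @param objective a reaction id (or ids summed with weight 1), or a full
#'   numeric selector of length `n`.
#' @return a `flux_distribution` with fields `fluxes`, `objective_values`
#'   (length 1) and `status` (`"optimal"`, `"infeasible"` or `"failed"`).
#'   Non-optimal statuses carry `NA` fluxes, never silent zeros.
#' @examples
#' fba(toy_model("chain"), "biomass")
#' @export
fba <- function(model, objective) {
  sel <- as_selector(model, objective)
  sol <- solve_lp(sel, model$S, model$lower_bounds, model$upper_bounds)
  new_flux_distribution(model, sol$v, sol$objective, sol$status)
}

#' Lexicographic (trilevel) flux-balance analysis
#'
#' Solves a sequence of 1--3 nested LPs over the steady-state polytope: the
#' first (innermost) objective is maximized, its optimum is fixed via the
#' constraint \eqn{c^\top v \ge z^* - \mathrm{fix\_tol}\cdot\max(1, |z^*|)},
#' and the next objective is maximized over the remaining optimal face.
#' This is the lexicographic reading of a trilevel program with nested
#' \eqn{\max} operators: outer levels optimize over the optimal sets of the
#' inner ones. Only the objective values are guaranteed reproducible when
#' the final optimal face is degenerate; the returned vertex is whichever
#' the simplex solver lands on.
#'
#' @param model a `metabolic_model`.
#' @param objectives ordered objectives, highest priority first: a character
#'   vector of reaction ids (one per level) or a list of selectors accepted
#'   by [fba()]. At most 3 levels.
#' @param fix_tol relative tolerance used when fixing each solved level
#'   (default `1e-9`); keeps the optimal face numerically non-empty while
#'   letting later levels leak at most `~fix_tol * |z|` of earlier optima.
#' @return a `flux_distribution`; `objective_values` holds one optimum per
#'   level, named by level when objectives are reaction ids.
#' @examples
#' lexicographic_fba(toy_model("branch"), c("biomass", "product"))
#' @export
lexicographic_fba <- function(model, objectives, fix_tol = 1e-9) {
  if (is.character(objectives)) objectives <- as.list(objectives)
  if (length(objectives) < 1 || length(objectives) > 3)
    stop("between 1 and 3 objective levels are supported", call. = FALSE)
  sels <- lapply(objectives, as_selector, model = model)
  level_names <- vapply(seq_along(objectives), function(i) {
    o <- objectives[[i]]
    if (is.character(o) && length(o) == 1) o else paste0("level", i)
  }, character(1))
  extra <- list()
  optima <- numeric(0)
  sol <- NULL
  for (l in seq_along(sels)) {
    sol <- solve_lp(sels[[l]], model$S, model$lower_bounds, model$upper_bounds,
                    extra_ge = extra)
    if (sol$status != "optimal")
      stop(sprintf("lexicographic level %d ('%s') is %s after fixing previous levels",
                   l, level_names[l], sol$status), call. = FALSE)
    optima <- c(optima, sol$objective)
    extra <- c(extra, list(list(a = sels[[l]],
                                rhs = sol$objective - fix_tol * max(1, abs(sol$objective)))))
  }
  new_flux_distribution(model, sol$v, stats::setNames(optima, level_names), "optimal")
}

#' Pareto front of objective-space points
#'
#' Returns the non-dominated subset of a point cloud under maximization of
#' every coordinate: a point is dominated when another point is at least as
#' good in all coordinates and strictly better in one. Used to extract
#' trade-off curves (e.g. biomass vs. by-product secretion across
#' conditions, split by an aerobic flag).
#'
#' @param points numeric matrix, one row per point, `d >= 2` columns.
#' @return the non-dominated rows, de-duplicated, ordered by the first
#'   coordinate (row names preserved). Empty input returns an empty matrix.
#' @examples
#' pareto_front(rbind(c(1, 1), c(2, 0), c(0, 2), c(0.5, 0.5)))
#' @export
pareto_front <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) == 0) return(points)
  if (ncol(points) < 2) stop("points must have at least 2 coordinates", call. = FALSE)
  if (any(!is.finite(points))) stop("points must be finite", call. = FALSE)
  points <- points[!duplicated(points), , drop = FALSE]
  n <- nrow(points)
  keep <- vapply(seq_len(n), function(i) {
    !any(vapply(seq_len(n), function(j) {
      j != i && all(points[j, ] >= points[i, ]) && any(points[j, ] > points[i, ])
    }, logical(1)))
  }, logical(1))
  front <- points[keep, , drop = FALSE]
  front[order(front[, 1]), , drop = FALSE]
}

#' Write a flux distribution as two-column delimited text
#'
#' @param fd a `flux_distribution`.
#' @param path output path; columns `reaction_id` and `flux`, tab-separated.
#' @return `path`, invisibly.
#' @export
write_fluxes <- function(fd, path) {
  utils::write.table(
    data.frame(reaction_id = names(fd$fluxes), flux = unname(fd$fluxes)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
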
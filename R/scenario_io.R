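#' Serialize a synthetic scenario to YAML
#'
#' Writes every generator parameter (component means, cv, weight
#' trajectories, correlation targets, cytometry fractions, pY scales,
#' counts, seed) so a scenario can travel as configuration and be rebuilt
#' exactly.
#'
#' @param scn a [synthetic_scenario].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scenario_yaml <- function(scn, path) {
  stopifnot(inherits(scn, "synthetic_scenario"))
  df2list <- function(df) lapply(df, function(col) as.vector(col))
  obj <- list(
    component_means = list(rows = rownames(scn$component_means),
                           cols = colnames(scn$component_means),
                           values = as.vector(t(scn$component_means))),
    component_cv = scn$component_cv,
    weights = df2list(scn$weights),
    n_per_condition = scn$n_per_condition,
    correlation_targets = df2list(scn$correlation_targets),
    ## named vectors become YAML maps so the names survive
    cytometry_fractions = lapply(scn$cytometry_fractions, function(x) {
      if (length(x) > 1L || !is.null(names(x))) as.list(x) else x
    }),
    py_scales = df2list(scn$py_scales),
    n_counted = scn$n_counted,
    seed = scn$seed)
  ## 17 significant digits round-trip IEEE doubles exactly
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' Rebuild a synthetic scenario from YAML
#'
#' @param path a file written by [write_scenario_yaml()].
#' @return A [synthetic_scenario] equal to the one serialized.
#' @export
read_scenario_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  cm <- matrix(obj$component_means$values,
               nrow = length(obj$component_means$rows), byrow = TRUE,
               dimnames = list(obj$component_means$rows,
                               obj$component_means$cols))
  list2df <- function(l) as.data.frame(l, stringsAsFactors = FALSE)
  suppressWarnings(synthetic_scenario(
    component_means = cm,
    component_cv = obj$component_cv,
    weights = list2df(obj$weights),
    n_per_condition = obj$n_per_condition,
    correlation_targets = list2df(obj$correlation_targets),
    cytometry_fractions = lapply(obj$cytometry_fractions, function(x) {
      if (is.list(x)) unlist(x) else x
    }),
    py_scales = list2df(obj$py_scales),
    n_counted = obj$n_counted,
    seed = obj$seed))
}
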
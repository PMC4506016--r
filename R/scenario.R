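## Scenario files: a YAML description of grid, schedule, effort and truth,
## so a synthetic study system can be regenerated from one small text file.

#' Write a simulation scenario as YAML
#'
#' @param scenario A list with components `grid` (n_x, n_y, cell_size,
#'   origin), `schedule` (data frame year/season), `effort` (params for
#'   [simulate_effort()]) and `truth` (a [truth_scenario()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  tr <- scenario$truth
  yaml::write_yaml(list(
    grid = scenario$grid,
    schedule = lapply(seq_len(nrow(scenario$schedule)), function(i)
      list(year = scenario$schedule$year[i],
           season = scenario$schedule$season[i])),
    effort = scenario$effort,
    truth = list(beta_occ = as.list(tr$beta_occ),
                 beta_sgt = as.list(tr$beta_sgt), theta = tr$theta,
                 group_mean = tr$group_mean, group_theta = tr$group_theta)
  ), path)
  invisible(path)
}

#' Read a simulation scenario from YAML
#'
#' @param path Scenario file written by [write_scenario()].
#' @return A scenario list (see [write_scenario()]).
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  sched <- do.call(rbind, lapply(y$schedule, function(s)
    data.frame(year = as.integer(s$year), season = s$season)))
  list(grid = y$grid, schedule = sched, effort = y$effort,
       truth = truth_scenario(
         beta_occ = unlist(y$truth$beta_occ),
         beta_sgt = unlist(y$truth$beta_sgt),
         theta = y$truth$theta, group_mean = y$truth$group_mean,
         group_theta = y$truth$group_theta))
}

#' Generate a full synthetic dataset from a scenario
#'
#' @param scenario Scenario list (see [read_scenario()]).
#' @param seed Master integer seed.
#' @return List: `grid`, `env`, `effort`, `dataset`.
#' @export
simulate_scenario <- function(scenario, seed = 1) {
  g <- scenario$grid
  grid <- generate_grid(g$n_x, g$n_y, g$cell_size,
                        if (is.null(g$origin)) c(0, 0) else unlist(g$origin))
  env <- generate_environment(grid, scenario$schedule, seed = seed)
  eff <- simulate_effort(grid, scenario$schedule, scenario$effort, seed)
  ds <- simulate_observations(env, eff, scenario$truth, seed)
  list(grid = grid, env = env, effort = eff, dataset = ds)
}
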
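# Versioned run configuration: the booster hyperparameters and the
# workflow thresholds, loadable from YAML so results are reproducible
# across releases of the underlying learner.

#' Default workflow configuration
#'
#' @return list with the booster settings and the workflow thresholds
#'   (`rs_min = 0.25`, `test_size = 10`, `n_folds = 5`,
#'   `final_seeds = 10`, `yrand_runs = 10`).
#' @export
default_config <- function() {
  list(booster = list(learning_rate = 0.05, n_trees = 700L, max_depth = 6L,
                      row_subsample = 0.8, col_subsample = 0.8,
                      aggregate = "mean"),
       rs_min = 0.25,
       test_size = 10L,
       n_folds = 5L,
       final_seeds = 10L,
       yrand_runs = 10L)
}

#' Load a workflow configuration from YAML
#'
#' Fields absent from the file keep their [default_config()] values;
#' unknown fields are an error.
#'
#' @param path path to a YAML file, or `NULL` for the defaults.
#' @return a configuration list as in [default_config()].
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  if (!is.null(user$booster)) {
    unknown_b <- setdiff(names(user$booster), names(cfg$booster))
    if (length(unknown_b) > 0)
      stop("unknown booster field(s): ", paste(unknown_b, collapse = ", "))
    cfg$booster[names(user$booster)] <- user$booster
    user$booster <- NULL
  }
  cfg[names(user)] <- user
  cfg
}

config_booster <- function(cfg, seed = 0L) {
  booster_config(learning_rate = cfg$booster$learning_rate,
                 n_trees = cfg$booster$n_trees,
                 max_depth = cfg$booster$max_depth,
                 row_subsample = cfg$booster$row_subsample,
                 col_subsample = cfg$booster$col_subsample,
                 seed = seed,
                 aggregate = cfg$booster$aggregate)
}
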
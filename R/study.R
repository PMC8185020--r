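# End-to-end study orchestration: configuration, the full
# simulate -> efficiency -> behavioral-report pipeline, optional volume-map
# analysis, and recomputation of the published behavioral statistics from
# the shipped per-subject table.

#' Study configuration
#'
#' @param n_parallel,n_serial Subjects per group.
#' @param runs_per_subject Training runs per subject (18 in the study).
#' @param te_mean,te_sd Named (`parallel`, `serial`) group mean/SD of the
#'   best-run training efficiency, percent.
#' @param params An `nf_sim_params`.
#' @param margin Minimum TE separation between the designated best run and
#'   the others, percent.
#' @param seed Master seed; every subject's seed derives from it.
#' @param volumes Also simulate small 4D volume runs and run the map
#'   pipeline (conjunction, disjunction, labeling) on the groups' mETRs.
#' @param grid_shape Volume grid when `volumes = TRUE`.
#' @return An `nf_study_config` list.
#' @export
study_config <- function(n_parallel = 10, n_serial = 10, runs_per_subject = 18,
                         te_mean = c(parallel = 1.27, serial = 2.3),
                         te_sd = c(parallel = 0.8, serial = 1.0),
                         params = sim_params(), margin = 1, seed = 1,
                         volumes = FALSE, grid_shape = c(10, 10, 10)) {
  if (runs_per_subject != 18) {
    abort("The training protocol comprises 18 runs per subject.",
          class = "rtnf_config_error")
  }
  structure(list(n_parallel = n_parallel, n_serial = n_serial,
                 runs_per_subject = runs_per_subject,
                 te_mean = te_mean, te_sd = te_sd, params = params,
                 margin = margin, seed = seed, volumes = volumes,
                 grid_shape = grid_shape),
            class = "nf_study_config")
}

#' Read and write study configurations (YAML)
#'
#' Configurations round-trip losslessly through YAML; seeds are always
#' explicit in the file.
#'
#' @param config An `nf_study_config`.
#' @param path YAML file path.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "nf_study_config"))
  obj <- unclass(config)
  obj$params <- unclass(obj$params)
  obj$params$amplitudes <- lapply(obj$params$amplitudes, as.list)
  # yaml drops names of atomic vectors; store named quantities as maps
  obj$te_mean <- as.list(obj$te_mean)
  obj$te_sd <- as.list(obj$te_sd)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  obj <- yaml::read_yaml(path)
  amps <- lapply(obj$params$amplitudes, function(a) unlist(a) %||% numeric())
  params <- do.call(sim_params, c(obj$params[setdiff(names(obj$params), "amplitudes")],
                                  list(amplitudes = amps)))
  study_config(n_parallel = obj$n_parallel, n_serial = obj$n_serial,
               runs_per_subject = obj$runs_per_subject,
               te_mean = unlist(obj$te_mean), te_sd = unlist(obj$te_sd),
               params = params, margin = obj$margin, seed = obj$seed,
               volumes = obj$volumes, grid_shape = unlist(obj$grid_shape))
}

#' Run a full simulated study
#'
#' Simulates both groups, estimates every subject's per-run training
#' efficiency with the ROI GLM, selects each mETR, and produces the
#' behavioral report (group summaries and the four tests). Deterministic
#' for a fixed configuration: rerunning yields an identical behavioral
#' table. The manifest maps every subject to the seed that generated it.
#'
#' @param config An `nf_study_config`.
#' @return An `nf_study`: list with `behavior` (tibble), `report`
#'   (`nf_behavior_report`), `design` (the group design), `manifest`
#'   (tibble of subject seeds) and `config`. When `config$volumes` is TRUE,
#'   also `maps` (group/conjunction/disjunction results and label reports).
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "nf_study_config"))
  design <- simulate_group(config$n_parallel, config$n_serial,
                           te_mean = config$te_mean, te_sd = config$te_sd,
                           params = config$params, margin = config$margin,
                           seed = config$seed)
  behavior <- estimate_group(design)
  report <- behavior_report(behavior)
  out <- list(behavior = behavior, report = report, design = design,
              manifest = dplyr::select(as_tibble(design), "subject", "group", "seed"),
              config = config)
  if (isTRUE(config$volumes)) {
    out$maps <- study_volume_maps(config)
  }
  structure(out, class = "nf_study")
}

# Desk-scale volume arm of a study: per group, simulate one mETR volume run
# per subject with an active region, run the first level, form the group
# map, then conjunction, disjunctions, and labeling against a synthetic
# template set.
study_volume_maps <- function(config, n_perm = 200) {
  gs <- config$grid_shape
  region <- function(lo, hi) {
    m <- array(FALSE, gs)
    m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    m
  }
  shared <- region(c(2, 2, 2), pmin(gs, c(4, 4, 4)))
  layouts <- list(
    parallel = list(list(mask = shared, amplitudes = c(think = 2))),
    serial = list(list(mask = shared, amplitudes = c(think = 2)))
  )
  schedules <- list(parallel = build_parallel_schedule(),
                    serial = build_serial_schedule())
  groups <- lapply(names(layouts), function(g) {
    n_sub <- if (g == "parallel") config$n_parallel else config$n_serial
    copes <- lapply(seq_len(n_sub), function(i) {
      vr <- simulate_volume_run(gs, layouts[[g]], schedules[[g]],
                                params = config$params,
                                seed = child_seed(config$seed, 1000 + i +
                                                    1e4 * (g == "serial")))
      fl <- first_level_lsa(vr, use_motion = FALSE)
      contrast <- if (g == "parallel") "think" else "overall"
      fl[[contrast]]$cope
    })
    z <- group_one_sample(copes)
    thr <- cluster_threshold(z, 3.1, 0.05, n_perm = n_perm,
                             seed = child_seed(config$seed, 77))
    list(z = z, thresholded = thr)
  })
  names(groups) <- names(layouts)
  conj <- conjunction(groups$parallel$z, groups$serial$z, n_perm = n_perm,
                      seed = child_seed(config$seed, 78))
  dis_p <- disjunction(groups$parallel$z, conj, n_perm = n_perm,
                       seed = child_seed(config$seed, 79))
  dis_s <- disjunction(groups$serial$z, conj, n_perm = n_perm,
                       seed = child_seed(config$seed, 80))
  templates <- make_template_set(gs, n_templates = 10,
                                 seed = child_seed(config$seed, 81))
  labels <- lapply(groups, function(g) spatial_correlation(g$z, templates))
  overlap <- overlap_map(dis_p$map, dis_s$map, conj$map)
  list(groups = groups, conjunction = conj,
       disjunction = list(parallel = dis_p, serial = dis_s),
       label_reports = labels, overlap = overlap)
}

#' @export
print.nf_study <- function(x, ...) {
  cat(sprintf("<nf_study: %d + %d subjects, seed %s>\n",
              x$config$n_parallel, x$config$n_serial,
              format(x$config$seed)))
  print(x$report)
  invisible(x)
}

#' Recompute the published behavioral statistics
#'
#' Recomputes, from the shipped per-subject behavioral table, the group
#' means/SDs of training efficiency, group medians of the mETR position,
#' the Shapiro-Wilk normality checks, Welch's t-test on TE and the
#' Mann-Whitney test on mETR positions.
#'
#' @param table Behavioral table; defaults to the shipped study table.
#' @return An `nf_behavior_report`.
#' @export
reproduce_published_stats <- function(table = nf_behavior_table()) {
  behavior_report(table)
}
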
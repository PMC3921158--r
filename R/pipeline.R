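#' Pipeline configuration
#'
#' Collects every tunable of the simulate -> preprocess -> connectivity ->
#' graph -> statistics chain. Defaults reproduce the standard analysis
#' layout: 26-channel 10/20 montage at 500 Hz, six canonical bands, six
#' 4096-sample epochs, frontal/posterior clusters, 50 surrogate networks,
#' alpha .05, and an 8 vs 12 subject two-group synthetic cohort.
#'
#' @param montage a [montage()].
#' @param bands named list of [band_def()] (default [eeg_bands()]).
#' @param n_epochs,epoch_length epoching geometry.
#' @param clusters list with `frontal` and `posterior` label vectors.
#' @param n_surrogates surrogate networks per graph.
#' @param alpha significance level for the group tests.
#' @param seed master seed; mandatory in simulate mode.
#' @param mode input mode: `"simulate"`, `"ascii"` or `"edf"`.
#' @param n_per_group subjects per group (length 1 or 2), simulate mode.
#' @param template_a,template_b [group_template()]s for simulate mode;
#'   defaults are [fxs_like_template()] and [control_like_template()] built
#'   on the configured montage and duration.
#' @param input_manifest manifest path for ascii/edf modes.
#' @param out_dir optional output directory; when set, [run_pipeline()]
#'   writes result tables there.
#' @param stats_measures subject-level columns entered into the group
#'   t-tests (5 defaults: global PLI, long-range PLI, normalized clustering,
#'   normalized path length, small-world index).
#' @param graph_on_epochs if `TRUE` (default) graph metrics are computed
#'   per epoch and averaged; otherwise on the epoch-mean PLI matrix.
#' @param save_matrices if `TRUE`, write per-subject/band connectivity
#'   matrices under `out_dir`.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(montage = default_montage(),
                            bands = eeg_bands(),
                            n_epochs = 6,
                            epoch_length = 4096,
                            clusters = default_clusters(),
                            n_surrogates = 50,
                            alpha = 0.05,
                            seed = NULL,
                            mode = c("simulate", "ascii", "edf"),
                            n_per_group = c(8, 12),
                            template_a = NULL,
                            template_b = NULL,
                            input_manifest = NULL,
                            out_dir = NULL,
                            stats_measures = c("global_pli", "long_range",
                                               "clustering_norm",
                                               "path_length_norm",
                                               "small_world"),
                            graph_on_epochs = TRUE,
                            save_matrices = FALSE) {
  mode <- match.arg(mode)
  missing_labels <- setdiff(c(clusters$frontal, clusters$posterior),
                            montage$labels)
  if (length(missing_labels) > 0)
    stop("cluster label(s) not in montage: ",
         paste(missing_labels, collapse = ", "))
  if (mode == "simulate") {
    if (is.null(seed)) stop("seed is mandatory in simulate mode")
    duration <- n_epochs * epoch_length / montage$sampling_rate
    base <- simulation_config(n_channels = length(montage$labels),
                              sampling_rate = montage$sampling_rate,
                              duration = duration,
                              channel_labels = montage$labels)
    if (is.null(template_a)) template_a <- fxs_like_template(base)
    if (is.null(template_b)) template_b <- control_like_template(base)
  } else if (is.null(input_manifest)) {
    stop("input_manifest is required in ", mode, " mode")
  }
  structure(list(montage = montage, bands = bands,
                 n_epochs = n_epochs, epoch_length = epoch_length,
                 clusters = clusters, n_surrogates = n_surrogates,
                 alpha = alpha, seed = seed, mode = mode,
                 n_per_group = n_per_group,
                 template_a = template_a, template_b = template_b,
                 input_manifest = input_manifest, out_dir = out_dir,
                 stats_measures = stats_measures,
                 graph_on_epochs = graph_on_epochs,
                 save_matrices = save_matrices),
            class = "pipeline_config")
}

# stable rolling hash of the YAML rendering of the config
config_hash <- function(config) {
  txt <- yaml::as.yaml(lapply(unclass(config), function(x)
    if (is.list(x)) rapply(unclass(x), as.character, how = "replace") else
      as.character(x)))
  codes <- utf8ToInt(txt)
  h <- 0
  for (cd in codes) h <- (h * 31 + cd) %% 2147483647
  sprintf("%08x", h)
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys mirror the [pipeline_config()] arguments; `montage`
#' takes `labels` and `sampling_rate`, `bands` a map of name to
#' `[low, high]`, `clusters` the two label lists, and `templates` a map
#' `a:`/`b:` of per-band coupling strengths for the built-in coupling
#' pair sets.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  mont <- if (!is.null(y$montage))
    montage(y$montage$labels,
            if (!is.null(y$montage$sampling_rate)) y$montage$sampling_rate else 500)
  else default_montage()
  args$montage <- mont
  if (!is.null(y$bands))
    args$bands <- stats::setNames(
      lapply(names(y$bands), function(nm)
        band_def(nm, y$bands[[nm]][1], y$bands[[nm]][2])),
      names(y$bands))
  for (key in c("n_epochs", "epoch_length", "n_surrogates", "alpha", "seed",
                "mode", "n_per_group", "input_manifest", "out_dir",
                "stats_measures", "graph_on_epochs", "save_matrices"))
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  if (!is.null(y$clusters)) args$clusters <- y$clusters
  if (!is.null(y$templates)) {
    n_ep <- if (!is.null(y$n_epochs)) y$n_epochs else 6
    ep_len <- if (!is.null(y$epoch_length)) y$epoch_length else 4096
    base <- simulation_config(n_channels = length(mont$labels),
                              sampling_rate = mont$sampling_rate,
                              duration = n_ep * ep_len / mont$sampling_rate,
                              channel_labels = mont$labels)
    args$template_a <- group_template(
      if (!is.null(y$templates$a$label)) y$templates$a$label else "group_a",
      base, template_couplings(y$templates$a$strengths))
    args$template_b <- group_template(
      if (!is.null(y$templates$b$label)) y$templates$b$label else "group_b",
      base, template_couplings(y$templates$b$strengths))
  }
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline
#'
#' For every subject and band: zero-phase band-pass, epoching,
#' analytic-signal phases, per-epoch PLI matrices and their mean; global
#' and frontal/posterior cluster PLI; weighted graph metrics normalized
#' against edge-shuffled surrogates (per epoch, then averaged, by default);
#' band power. Then, per band and measure, log-transformed pooled
#' two-tailed t-tests with partial eta squared across groups, and per-group
#' PLI-power correlations.
#'
#' @param config a [pipeline_config()].
#' @return List of class `"pipeline_result"`: `subject_metrics` (data
#'   frame), `group_stats`, `correlations`, `connectivity` (nested list of
#'   subject-mean matrices), `manifest`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- switch(config$mode,
    simulate = generate_cohort(config$template_a, config$template_b,
                               config$n_per_group, config$seed),
    ascii = read_cohort_ascii(config$input_manifest, config$montage),
    edf = read_cohort_edf(config$input_manifest, config$montage))
  seed0 <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  rows <- list()
  conn <- list()
  for (si in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[si]]
    conn[[s$id]] <- list()
    for (bi in seq_along(config$bands)) {
      band <- config$bands[[bi]]
      ep <- make_epochs(bandpass(s$recording, band),
                        config$n_epochs, config$epoch_length)
      phases <- lapply(ep$epochs, instantaneous_phase)
      mats <- lapply(phases, epoch_connectivity, measure = "pli")
      m <- Reduce(`+`, mats) / length(mats)
      conn[[s$id]][[band$name]] <- m
      cl <- cluster_means(m, config$clusters$frontal, config$clusters$posterior)
      gseed <- subject_seed(seed0 + 7777,
                            (si - 1) * 997 + (bi - 1) * 61)
      gm <- if (config$graph_on_epochs) {
        per_ep <- lapply(seq_along(mats), function(e)
          normalize_metrics(mats[[e]], config$n_surrogates,
                            seed = gseed + e))
        avg <- function(f) mean(vapply(per_ep, `[[`, 0, f))
        list(clustering = avg("clustering"),
             path_length = avg("path_length"),
             clustering_norm = avg("clustering_norm"),
             path_length_norm = avg("path_length_norm"),
             small_world = avg("small_world"))
      } else {
        normalize_metrics(m, config$n_surrogates, seed = gseed)
      }
      pw <- mean(sapply(ep$epochs, function(e) mean(e^2)))
      rows[[length(rows) + 1]] <- data.frame(
        subject = s$id, group = s$group, band = band$name,
        global_pli = mean(m[upper.tri(m)]),
        frontal_short = cl$frontal_short,
        posterior_short = cl$posterior_short,
        long_range = cl$long_range,
        clustering = gm$clustering,
        path_length = gm$path_length,
        clustering_norm = gm$clustering_norm,
        path_length_norm = gm$path_length_norm,
        small_world = gm$small_world,
        band_power = pw,
        stringsAsFactors = FALSE)
    }
  }
  subject_metrics <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(subject = character(), group = character(), band = character(),
               global_pli = numeric(), frontal_short = numeric(),
               posterior_short = numeric(), long_range = numeric(),
               clustering = numeric(), path_length = numeric(),
               clustering_norm = numeric(), path_length_norm = numeric(),
               small_world = numeric(), band_power = numeric(),
               stringsAsFactors = FALSE)

  group_stats <- compute_group_stats(subject_metrics, cohort$groups,
                                     names(config$bands),
                                     config$stats_measures)
  correlations <- compute_pli_power_correlations(subject_metrics,
                                                 cohort$groups,
                                                 names(config$bands))

  manifest <- list(seed = config$seed,
                   mode = config$mode,
                   groups = cohort$groups,
                   n_subjects = length(cohort$subjects),
                   package_version = as.character(utils::packageVersion("plinet")),
                   config_hash = config_hash(config),
                   subjects = data.frame(
                     subject = vapply(cohort$subjects, `[[`, "", "id"),
                     group = vapply(cohort$subjects, `[[`, "", "group"),
                     seed = vapply(cohort$subjects, function(s)
                       as.integer(if (is.null(s$seed)) NA else s$seed), 1L),
                     stringsAsFactors = FALSE))

  res <- structure(list(subject_metrics = subject_metrics,
                        group_stats = group_stats,
                        correlations = correlations,
                        connectivity = conn,
                        manifest = manifest,
                        config = config),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) {
    write_results(res, config$out_dir)
    yaml::write_yaml(manifest[setdiff(names(manifest), "subjects")],
                     file.path(config$out_dir, "run_manifest.yaml"))
    utils::write.table(manifest$subjects,
                       file.path(config$out_dir, "subjects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (isTRUE(config$save_matrices)) {
      mdir <- file.path(config$out_dir, "matrices")
      dir.create(mdir, showWarnings = FALSE)
      for (sid in names(conn))
        for (bn in names(conn[[sid]]))
          utils::write.table(format(conn[[sid]][[bn]], digits = 15),
                             file.path(mdir, paste0(sid, "_", bn, ".tsv")),
                             sep = "\t", quote = FALSE)
    }
  }
  res
}

compute_group_stats <- function(sm, groups, band_names, measures) {
  out <- list()
  for (bn in band_names) {
    for (ms in measures) {
      a <- sm[[ms]][sm$band == bn & sm$group == groups[1]]
      b <- sm[[ms]][sm$band == bn & sm$group == groups[2]]
      if (length(a) < 2 || length(b) < 2) next
      st <- independent_t(log_transform(a), log_transform(b))
      out[[length(out) + 1]] <- data.frame(
        band = bn, measure = ms, t = st$t, df = st$df, p = st$p,
        eta_p2 = st$eta_p2, n_a = length(a), n_b = length(b),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) > 0) do.call(rbind, out) else
    data.frame(band = character(), measure = character(), t = numeric(),
               df = numeric(), p = numeric(), eta_p2 = numeric(),
               n_a = integer(), n_b = integer(), stringsAsFactors = FALSE)
}

compute_pli_power_correlations <- function(sm, groups, band_names) {
  out <- list()
  for (bn in band_names) {
    for (g in groups) {
      x <- sm$global_pli[sm$band == bn & sm$group == g]
      y <- sm$band_power[sm$band == bn & sm$group == g]
      if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) next
      ct <- pearson_correlation(x, y)
      out[[length(out) + 1]] <- data.frame(
        band = bn, group = g, r = ct$r, n = ct$n, p = ct$p,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) > 0) do.call(rbind, out) else
    data.frame(band = character(), group = character(), r = numeric(),
               n = integer(), p = numeric(), stringsAsFactors = FALSE)
}

#' Read a cohort from an EDF manifest
#'
#' Manifest TSV with columns `subject`, `group` and `file` (one EDF per
#' subject, path relative to the manifest).
#'
#' @param manifest_path path to the manifest TSV.
#' @param montage a [montage()]; channels are matched case-insensitively.
#' @return An `eeg_cohort`-like list.
#' @export
read_cohort_edf <- function(manifest_path, montage = default_montage()) {
  mf <- utils::read.table(manifest_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  subjects <- lapply(seq_len(nrow(mf)), function(i) {
    list(id = mf$subject[i], group = mf$group[i], seed = NA_integer_,
         recording = read_edf(file.path(base, mf$file[i]), montage))
  })
  structure(list(subjects = subjects, groups = unique(mf$group)),
            class = "eeg_cohort")
}
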
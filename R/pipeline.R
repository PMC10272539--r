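#' Study configuration
#'
#' Collects all inputs and tunable parameters of a pre- vs post-SCS
#' ischemia study. Spike data come either from a spike table plus adjacency
#' map or from a [synth_spike_config()]; electrograms likewise from an
#' [egm_set()] or a [synth_egm_config()]. Electrogram beats are classified
#' against `egm_timeline` (epochs named as in the main timeline), which
#' allows a compact per-epoch electrogram record alongside the full-length
#' neural timeline.
#'
#' @param timeline a [protocol_timeline()] for the neural record.
#' @param spikes spike tibble, or `NULL` when `synth_spikes` is given.
#' @param adjacency electrode adjacency list (required with `spikes`).
#' @param synth_spikes optional [synth_spike_config()].
#' @param egm optional [egm_set()]; `NULL` when `synth_egm` is given or the
#'   electrogram stage is skipped.
#' @param egm_timeline [protocol_timeline()] for the electrogram record.
#' @param synth_egm optional [synth_egm_config()].
#' @param alpha significance level used throughout.
#' @param artifact_tol_ms cross-electrode artifact tolerance (ms).
#' @param iml_window_ms,iml_min_frac,iml_max_latency_sd_ms antidromic
#'   identification parameters, see [identify_iml()].
#' @param st_threshold_mv ischemic-zone ST criterion (mV).
#' @param dor_metric `"rt"` or `"ari"`, see [compute_dor()].
#' @param sync_window_ms,sync_jitter_ms,sync_surrogates,sync_epochs
#'   synchrony parameters, see [pairwise_synchrony()].
#' @param max_sync_neurons cap on the DH pool entering the pairwise
#'   synchrony stage (largest-n first by id); `NULL` for no cap.
#' @param flag_outliers add a median-absolute-deviation outlier flag to the
#'   delta table (flag only; nothing is removed).
#' @param stages pipeline stages to run.
#' @param seed master seed: fills in generator seeds when those are unset
#'   and drives the synchrony surrogates.
#' @return A list of class `study_config`.
#' @export
study_config <- function(timeline = default_study_timeline(),
                         spikes = NULL, adjacency = NULL,
                         synth_spikes = NULL,
                         egm = NULL, egm_timeline = NULL, synth_egm = NULL,
                         alpha = 0.05, artifact_tol_ms = 0.5,
                         iml_window_ms = 50, iml_min_frac = 0.6,
                         iml_max_latency_sd_ms = 5,
                         st_threshold_mv = 0.1, dor_metric = "rt",
                         sync_window_ms = 40, sync_jitter_ms = 200,
                         sync_surrogates = 1000,
                         sync_epochs = c("lad_pre", "lad_post"),
                         max_sync_neurons = 20, flag_outliers = FALSE,
                         stages = c("artifacts", "regions", "sensitivity",
                                    "modalities", "deltas", "egm",
                                    "synchrony", "group_tests"),
                         seed = 1) {
  if (is.null(spikes) && is.null(synth_spikes))
    stop("supply `spikes` or `synth_spikes`", call. = FALSE)
  if (!is.null(spikes) && is.null(adjacency) && "artifacts" %in% stages)
    stop("`adjacency` is required for the artifact stage", call. = FALSE)
  structure(as.list(environment()), class = "study_config")
}

mad_outlier_flag_ <- function(x, k = 5) {
  m <- median(x, na.rm = TRUE)
  s <- mad(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(FALSE, length(x)))
  abs(x - m) > k * s
}

#' Run the full pre- vs post-SCS study pipeline
#'
#' Orchestrates: artifact rejection, antidromic region labelling,
#' ischemia-sensitivity screening on the pre-SCS occlusion, modality
#' labelling of the sensitive neurons, firing-rate deltas for the same
#' neurons followed across all four response epochs, electrogram metrics
#' (ARI maps, ischemic zone, ARI shortening pre/post, dispersion of
#' repolarization per epoch), pairwise synchrony, and the group-level
#' comparisons. Any stage failure aborts with the stage name. The same
#' configuration and seed always produce an identical report.
#'
#' @param config a [study_config()].
#' @return An object of class `study_report`: a list of tibbles (see the
#'   `log` element for the stage funnel).
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  log <- list()
  note <- function(stage_name, n_in, n_out, what) {
    log[[length(log) + 1]] <<- tibble::tibble(
      stage = stage_name, n_in = n_in, n_out = n_out, unit = what)
  }
  tl <- config$timeline
  alpha <- config$alpha

  # --- input / synthesis ---------------------------------------------------
  truth <- NULL
  adjacency <- config$adjacency
  if (!is.null(config$synth_spikes)) {
    sc <- config$synth_spikes
    if (is.null(sc$seed)) sc$seed <- config$seed
    pop <- stage("synth_spikes", gen_spike_population(sc, tl))
    spikes <- pop$spikes
    truth <- pop$truth
    if (is.null(adjacency)) adjacency <- pop$adjacency
  } else {
    spikes <- config$spikes
  }
  assert_spike_table_(spikes)
  n0 <- nrow(spikes)

  # --- artifact rejection --------------------------------------------------
  if ("artifacts" %in% config$stages) {
    spikes <- stage("artifacts",
                    remove_artifacts(spikes, adjacency, config$artifact_tol_ms))
    note("artifacts", n0, nrow(spikes), "spikes")
  }

  # --- antidromic region labels -------------------------------------------
  regions <- NULL
  if ("regions" %in% config$stages) {
    pulses <- if (length(tl$stim_pulses) > 0) tl$stim_pulses[[1]] else numeric(0)
    regions <- stage("regions",
                     classify_regions(spikes, pulses, config$iml_window_ms,
                                      config$iml_min_frac,
                                      config$iml_max_latency_sd_ms))
    note("regions", length(unique(spikes$neuron_id)),
         sum(regions$region == "IML"), "IML neurons")
  }

  # --- ischemia sensitivity (pre-SCS screen) -------------------------------
  sensitivity <- NULL
  sensitive_ids <- character(0)
  if ("sensitivity" %in% config$stages) {
    sensitivity <- stage("sensitivity",
                         classify_ischemia_sensitive(spikes, tl, alpha))
    sensitive_ids <- sensitivity$neuron_id[sensitivity$is_sensitive]
    note("sensitivity", nrow(sensitivity), length(sensitive_ids),
         "ischemia-sensitive neurons")
  }

  # --- modalities (reported for ischemia-sensitive neurons only) -----------
  modalities <- NULL
  if ("modalities" %in% config$stages) {
    modalities <- stage("modalities",
                        classify_modalities(spikes, tl, alpha))
    modalities <- modalities[modalities$neuron_id %in% sensitive_ids, ]
    note("modalities", length(sensitive_ids), nrow(modalities),
         "sensitive neurons labelled")
  }

  # --- response deltas: follow the sensitive roster across epochs ----------
  deltas <- NULL
  if ("deltas" %in% config$stages) {
    deltas <- stage("deltas", {
      spec <- list(c("lad_pre", "baseline_pre"), c("rep_pre", "baseline_pre"),
                   c("lad_post", "baseline_post"), c("rep_post", "baseline_post"))
      spec <- spec[vapply(spec, function(s)
        has_epoch(tl, s[1]) && has_epoch(tl, s[2]), logical(1))]
      d <- purrr::map_dfr(spec, function(s)
        response_delta(spikes, tl, s[1], s[2]))
      d <- d[d$neuron_id %in% sensitive_ids, ]
      if (config$flag_outliers)
        d <- d |> dplyr::group_by(.data$epoch) |>
          dplyr::mutate(outlier = mad_outlier_flag_(.data$delta_hz)) |>
          dplyr::ungroup()
      d
    })
    note("deltas", length(sensitive_ids),
         length(unique(deltas$neuron_id)), "neurons followed")
  }

  # --- electrogram metrics -------------------------------------------------
  egm_results <- NULL
  if ("egm" %in% config$stages &&
      (!is.null(config$egm) || !is.null(config$synth_egm))) {
    egm_results <- stage("egm", {
      etl <- config$egm_timeline
      if (is.null(etl)) stop("`egm_timeline` is required")
      if (!is.null(config$synth_egm)) {
        ec <- config$synth_egm
        if (is.null(ec$seed)) ec$seed <- config$seed + 1L
        egm <- gen_electrograms(ec, etl)$egm
      } else egm <- config$egm
      beats <- measure_beats(egm)
      epochs <- intersect(c("baseline_pre", "lad_pre", "baseline_post",
                            "lad_post"), etl$epochs$epoch)
      maps <- lapply(epochs, function(e)
        compute_ari(beats, epoch_window(etl, e)))
      names(maps) <- epochs
      dor <- purrr::map_dfr(epochs, function(e)
        dplyr::mutate(compute_dor(beats, epoch_window(etl, e),
                                  config$dor_metric), epoch = e, .before = 1))
      st <- beats[in_window_(beats$onset_s, epoch_window(etl, "lad_pre")), ] |>
        dplyr::group_by(.data$electrode_id) |>
        dplyr::summarise(st_mv = mean(.data$st_mv, na.rm = TRUE),
                         .groups = "drop")
      mask <- define_ischemic_zone(st, config$st_threshold_mv)
      short <- tibble::tibble(
        phase = c("pre", "post"),
        ari_shortening_ms = c(
          ari_shortening(maps$baseline_pre, maps$lad_pre, mask),
          if (all(c("baseline_post", "lad_post") %in% epochs))
            ari_shortening(maps$baseline_post, maps$lad_post, mask)
          else NA_real_)
      )
      list(beats = beats, maps = maps, st = st, ischemic_mask = mask,
           shortening = short, dor = dor)
    })
    note("egm", length(egm_results$maps$baseline_pre$electrode_id),
         length(egm_results$ischemic_mask), "ischemic electrodes")
  }

  # --- pairwise synchrony --------------------------------------------------
  synchrony <- NULL
  if ("synchrony" %in% config$stages && !is.null(regions)) {
    synchrony <- stage("synchrony", {
      pool <- regions
      dh_pool <- pool$neuron_id[pool$region == "DH" &
                                  pool$neuron_id %in% sensitive_ids]
      if (length(dh_pool) == 0) dh_pool <- pool$neuron_id[pool$region == "DH"]
      if (!is.null(config$max_sync_neurons))
        dh_pool <- head(sort(dh_pool), config$max_sync_neurons)
      keep <- pool[pool$neuron_id %in% dh_pool | pool$region == "IML", ]
      pairs <- pairwise_synchrony(spikes, keep, tl, config$sync_epochs,
                                  window_ms = config$sync_window_ms,
                                  jitter_half_width_ms = config$sync_jitter_ms,
                                  n_surrogates = config$sync_surrogates,
                                  alpha = alpha, seed = config$seed)
      list(pairs = pairs, summary = synchrony_summary(pairs))
    })
    note("synchrony", nrow(synchrony$pairs),
         sum(synchrony$pairs$significant, na.rm = TRUE), "significant pairs")
  }

  report <- structure(
    list(config = config, truth = truth, regions = regions,
         sensitivity = sensitivity, modalities = modalities, deltas = deltas,
         egm = egm_results, synchrony = synchrony,
         group_tests = NULL, log = dplyr::bind_rows(log)),
    class = "study_report"
  )
  if ("group_tests" %in% config$stages)
    report$group_tests <- stage("group_tests", group_compare(report))
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  print(x$log)
  invisible(x)
}

#' @exportS3Method generics::glance
glance.study_report <- function(x, ...) {
  tibble::tibble(
    n_neurons = if (is.null(x$sensitivity)) NA_integer_ else nrow(x$sensitivity),
    n_sensitive = if (is.null(x$sensitivity)) NA_integer_
                  else sum(x$sensitivity$is_sensitive),
    n_iml = if (is.null(x$regions)) NA_integer_ else sum(x$regions$region == "IML"),
    mean_delta_lad_pre = mean_delta_(x, "lad_pre"),
    mean_delta_lad_post = mean_delta_(x, "lad_post"),
    n_sync_significant = if (is.null(x$synchrony)) NA_integer_
                         else sum(x$synchrony$pairs$significant, na.rm = TRUE)
  )
}

mean_delta_ <- function(x, epoch) {
  if (is.null(x$deltas)) return(NA_real_)
  d <- x$deltas$delta_hz[x$deltas$epoch == epoch]
  if (length(d) == 0) NA_real_ else mean(d)
}

# Dunn's multiple-comparison z tests after a Friedman test.
# mat: n subjects x k conditions. Bonferroni-adjusted two-sided p.
dunn_friedman_ <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  ranks <- t(apply(mat, 1, rank))
  rbar <- colMeans(ranks)
  se <- sqrt(k * (k + 1) / (6 * n))
  cmp <- utils::combn(k, 2)
  m <- ncol(cmp)
  purrr::map_dfr(seq_len(m), function(i) {
    a <- cmp[1, i]; b <- cmp[2, i]
    z <- (rbar[a] - rbar[b]) / se
    tibble::tibble(
      comparison = paste(colnames(mat)[a], "vs", colnames(mat)[b]),
      statistic = z, n = n,
      p_value = 2 * pnorm(-abs(z)),
      p_adjusted = pmin(1, 2 * pnorm(-abs(z)) * m)
    )
  })
}

#' Group-level comparisons for a study report
#'
#' Non-parametric battery mirroring the study design: a Friedman test (with
#' Dunn's multiple-comparison z tests, Bonferroni-adjusted) across the four
#' response epochs of the per-neuron deltas; a Kruskal-Wallis test of the
#' pre-SCS occlusion delta across modality groups (multimodal taking
#' precedence over single labels); and paired Wilcoxon signed-rank tests of
#' the synchrony index pre vs post SCS per pair category. Groups with fewer
#' than 3 observations are skipped with a note.
#'
#' @param report a [run_study()] report (or a list with compatible
#'   `deltas`, `modalities`, `synchrony` elements).
#' @param alpha significance level (annotation only).
#' @return Tibble `test`, `comparison`, `n`, `statistic`, `p_value`,
#'   `p_adjusted`, `note`.
#' @export
group_compare <- function(report, alpha = 0.05) {
  out <- list()
  add <- function(test, comparison, n, statistic, p, p_adj = NA_real_,
                  note = NA_character_) {
    out[[length(out) + 1]] <<- tibble::tibble(
      test = test, comparison = comparison, n = n,
      statistic = statistic, p_value = p, p_adjusted = p_adj, note = note)
  }

  if (!is.null(report$deltas) && nrow(report$deltas) > 0) {
    wide <- tidyr::pivot_wider(report$deltas[c("neuron_id", "epoch", "delta_hz")],
                               names_from = "epoch", values_from = "delta_hz")
    mat <- as.matrix(wide[, -1, drop = FALSE])
    mat <- mat[stats::complete.cases(mat), , drop = FALSE]
    if (nrow(mat) >= 3 && ncol(mat) >= 2) {
      fr <- friedman.test(mat)
      add("friedman", "delta_hz across epochs", nrow(mat),
          unname(fr$statistic), fr$p.value)
      dn <- dunn_friedman_(mat)
      for (i in seq_len(nrow(dn)))
        add("dunn", dn$comparison[i], dn$n[i], dn$statistic[i],
            dn$p_value[i], dn$p_adjusted[i])
    } else {
      add("friedman", "delta_hz across epochs", nrow(mat), NA_real_,
          NA_real_, note = "skipped: fewer than 3 complete neurons")
    }
  }

  if (!is.null(report$modalities) && !is.null(report$deltas) &&
      nrow(report$modalities) > 0) {
    mod <- report$modalities |>
      dplyr::mutate(group = dplyr::case_when(
        .data$multimodal ~ "multimodal",
        .data$mechano ~ "mechanosensitive",
        .data$nociceptive ~ "nociceptive",
        TRUE ~ NA_character_)) |>
      dplyr::filter(!is.na(.data$group))
    d <- report$deltas[report$deltas$epoch == "lad_pre", ]
    mod <- dplyr::inner_join(mod, d, by = "neuron_id")
    sizes <- table(mod$group)
    if (length(sizes) >= 2 && all(sizes >= 3)) {
      kw <- kruskal.test(delta_hz ~ factor(group), data = mod)
      add("kruskal-wallis", "lad_pre delta_hz across modality groups",
          nrow(mod), unname(kw$statistic), kw$p.value)
    } else {
      add("kruskal-wallis", "lad_pre delta_hz across modality groups",
          nrow(mod), NA_real_, NA_real_,
          note = "skipped: group with fewer than 3 neurons")
    }
  }

  if (!is.null(report$synchrony) && nrow(report$synchrony$pairs) > 0) {
    pr <- report$synchrony$pairs
    eps <- unique(pr$epoch)
    if (all(c("lad_pre", "lad_post") %in% eps)) {
      for (cat in unique(pr$category)) {
        a <- pr[pr$category == cat & pr$epoch == "lad_pre" & pr$defined, ]
        b <- pr[pr$category == cat & pr$epoch == "lad_post" & pr$defined, ]
        key <- intersect(paste(a$ref_id, a$target_id),
                         paste(b$ref_id, b$target_id))
        x <- a$si[match(key, paste(a$ref_id, a$target_id))]
        y <- b$si[match(key, paste(b$ref_id, b$target_id))]
        if (length(key) >= 3 && any(x != y)) {
          wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE))
          add("wilcoxon", paste0("si ", cat, " lad_pre vs lad_post"),
              length(key), unname(wt$statistic), wt$p.value)
        } else {
          add("wilcoxon", paste0("si ", cat, " lad_pre vs lad_post"),
              length(key), NA_real_,
              if (length(key) >= 3) 1 else NA_real_,
              note = if (length(key) >= 3) "no differences" else
                "skipped: fewer than 3 pairs")
        }
      }
    }
  }

  if (length(out) == 0) return(tibble::tibble())
  dplyr::bind_rows(out)
}

#' Write a study report to disk
#'
#' One TSV per table, fixed column order, plus a long-format
#' [result_table()] (`results.tsv`) collecting the headline metrics.
#'
#' @param report a [run_study()] report.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, name) {
    if (!is.null(df) && nrow(df) > 0)
      utils::write.table(df, file.path(dir, name), sep = "\t",
                         row.names = FALSE, quote = FALSE)
  }
  wr(report$regions, "regions.tsv")
  wr(report$sensitivity, "sensitivity.tsv")
  wr(report$modalities, "modalities.tsv")
  wr(report$deltas, "deltas.tsv")
  wr(report$group_tests, "group_tests.tsv")
  wr(report$log, "log.tsv")
  if (!is.null(report$egm)) {
    maps <- purrr::map_dfr(names(report$egm$maps), function(e)
      dplyr::mutate(report$egm$maps[[e]], epoch = e, .before = 1))
    wr(maps, "ari_maps.tsv")
    wr(report$egm$dor, "dor.tsv")
    wr(report$egm$shortening, "ari_shortening.tsv")
  }
  if (!is.null(report$synchrony)) {
    wr(report$synchrony$pairs, "synchrony_pairs.tsv")
    wr(report$synchrony$summary, "synchrony_summary.tsv")
  }
  if (!is.null(report$deltas) && nrow(report$deltas) > 0) {
    rt <- result_table(report$deltas$neuron_id, report$deltas$epoch,
                       "delta_hz", report$deltas$delta_hz)
    write_result_table(rt, file.path(dir, "results.tsv"))
  }
  invisible(dir)
}
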
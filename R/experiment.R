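#' Random train/validation split
#'
#' @param n number of individuals.
#' @param train_size training-set size, strictly between 0 and `n`.
#' @param seed integer seed.
#' @return a list with sorted integer index vectors `train` and
#'   `validation`; disjoint, jointly covering `1:n`.
#' @export
split_train_validation <- function(n, train_size, seed = 1L) {
  if (train_size <= 0 || train_size >= n) {
    stop("train_size must be strictly between 0 and n", call. = FALSE)
  }
  set.seed(seed)
  train <- sort(sample.int(n, train_size))
  list(train = train, validation = setdiff(seq_len(n), train))
}

#' Scenario configuration for the replicated prediction experiment
#'
#' Describes a grid of QTL counts and heritabilities crossed with marker
#' panels and models, each cell replicated with fresh train/validation
#' splits. Defaults mirror the study design this package simulates:
#' QTL counts 50/100/250/500, heritabilities 0.5 and 0.2, panels mp1-mp7,
#' the three whole-genome regressions, 5 replicates of a 400-individual
#' training half.
#'
#' @param n_qtl integer vector of QTL counts.
#' @param h2 numeric vector of heritabilities.
#' @param panels character vector from `"mp1"` ... `"mp7"`.
#' @param models character vector from `"rrblup"`, `"bayesB"`, `"bayesC"`.
#' @param n_replicates replicates per grid cell.
#' @param train_size training individuals per replicate.
#' @param resample_qtl_per_replicate if `TRUE` (default) QTL positions and
#'   effects are re-drawn every replicate (panels are then rebuilt too);
#'   if `FALSE` one architecture per (n_qtl, h2) cell is reused across
#'   replicates.
#' @param accuracy_truth correlate predictions with true genetic values
#'   (`"genetic_value"`, default) or with phenotypes (`"phenotype"`); both
#'   are always recorded.
#' @param effect_distribution passed to [sample_effects()].
#' @param mcmc an [mcmc_settings()] template (its seed is overridden per
#'   replicate).
#' @param pi_zero,update_pi passed to the Bayes samplers.
#' @param master_seed integer seed from which all per-replicate seeds are
#'   derived by a counter scheme, so every cell is reproducible in
#'   isolation and results do not depend on execution order.
#' @return a list of class `scenario_config`.
#' @export
scenario_config <- function(n_qtl = c(50, 100, 250, 500),
                            h2 = c(0.5, 0.2),
                            panels = paste0("mp", 1:7),
                            models = c("rrblup", "bayesB", "bayesC"),
                            n_replicates = 5,
                            train_size = 400,
                            resample_qtl_per_replicate = TRUE,
                            accuracy_truth = c("genetic_value", "phenotype"),
                            effect_distribution = "standard_normal",
                            mcmc = mcmc_settings(),
                            pi_zero = 0.95,
                            update_pi = TRUE,
                            master_seed = 1L) {
  accuracy_truth <- match.arg(accuracy_truth)
  panels <- match.arg(panels, paste0("mp", 1:7), several.ok = TRUE)
  models <- match.arg(models, c("rrblup", "bayesB", "bayesC"), several.ok = TRUE)
  stopifnot(n_replicates >= 1, all(n_qtl >= 1), all(h2 > 0), all(h2 <= 1))
  structure(list(n_qtl = as.integer(n_qtl), h2 = h2, panels = panels,
                 models = models, n_replicates = as.integer(n_replicates),
                 train_size = as.integer(train_size),
                 resample_qtl_per_replicate = isTRUE(resample_qtl_per_replicate),
                 accuracy_truth = accuracy_truth,
                 effect_distribution = effect_distribution,
                 mcmc = mcmc, pi_zero = pi_zero, update_pi = isTRUE(update_pi),
                 master_seed = as.integer(master_seed)),
            class = "scenario_config")
}

# counter-based replicate seed: distinct odd multipliers per axis keep
# cells independent; kept below 2^31
replicate_seed <- function(master_seed, n_qtl, h2, replicate) {
  base <- (as.numeric(master_seed) %% 1e6) * 1009
  s <- base + n_qtl * 131071 + round(h2 * 100) * 8191 + replicate * 524287
  as.integer(s %% 2147483647L)
}

#' Run one replicate of a scenario cell
#'
#' Derives the replicate seed, draws (or reuses) the QTL architecture,
#' simulates the trait, splits train/validation, builds each requested
#' marker panel, fits each requested model on the training rows restricted
#' to the panel's loci, and records validation accuracy against both the
#' true genetic values and the phenotypes.
#'
#' @param panel_data a [genotype_panel()].
#' @param scenario a [scenario_config()].
#' @param n_qtl,h2 the grid cell to run.
#' @param replicate_index replicate number (1-based).
#' @param arch optional fixed [sample_architecture()] (used when
#'   `resample_qtl_per_replicate` is `FALSE`).
#' @return a tibble with one row per (panel, model): accuracy columns
#'   `accuracy` (configured truth), `accuracy_g`, `accuracy_y`, and the
#'   realised `panel_size`.
#' @export
run_replicate <- function(panel_data, scenario, n_qtl, h2, replicate_index,
                          arch = NULL) {
  seed <- replicate_seed(scenario$master_seed, n_qtl, h2, replicate_index)
  if (is.null(arch)) {
    arch <- sample_architecture(panel_data, n_qtl,
                                distribution = scenario$effect_distribution,
                                seed = seed)
  }
  trait <- simulate_trait(panel_data, arch, h2, seed = seed + 2L)
  n <- nrow(panel_data$dosages)
  split <- split_train_validation(n, scenario$train_size, seed = seed + 3L)
  truth_col <- if (scenario$accuracy_truth == "genetic_value") "g" else "y"

  panels <- build_panels(scenario$panels, arch, panel_data, seed = seed + 4L)
  purrr::map_dfr(scenario$panels, function(pk) {
    mp <- panels[[pk]]
    Xp <- panel_data$dosages[, mp$locus_index, drop = FALSE]
    Xtr <- Xp[split$train, , drop = FALSE]
    Xva <- Xp[split$validation, , drop = FALSE]
    ytr <- trait$y[split$train]
    purrr::map_dfr(scenario$models, function(md) {
      mcmc <- scenario$mcmc
      mcmc$seed <- seed + 5L
      fit <- suppressWarnings(switch(
        md,
        rrblup = fit_rrblup(Xtr, ytr),
        bayesB = fit_bayesB(Xtr, ytr, mcmc, pi_zero = scenario$pi_zero,
                            update_pi = scenario$update_pi),
        bayesC = fit_bayesC(Xtr, ytr, mcmc, pi_zero = scenario$pi_zero,
                            update_pi = scenario$update_pi)
      ))
      pred <- predict(fit, Xva)
      acc_g <- accuracy(pred, trait$g[split$validation])
      acc_y <- accuracy(pred, trait$y[split$validation])
      tibble::tibble(n_qtl = n_qtl, h2 = h2, panel = pk, model = md,
                     replicate = replicate_index,
                     panel_size = nrow(mp),
                     accuracy = if (truth_col == "g") acc_g else acc_y,
                     accuracy_g = acc_g, accuracy_y = acc_y)
    })
  })
}

#' Run the full replicated scenario grid
#'
#' Loops over every (n_qtl, h2) cell and replicate of the configured grid,
#' then aggregates per (cell, panel, model) means and standard deviations.
#'
#' @inheritParams run_replicate
#' @param verbose print progress lines.
#' @return an `accuracy_table`: a tibble with one row per
#'   (n_qtl, h2, panel, model) carrying `mean_accuracy`, `sd_accuracy`,
#'   the realised `panel_size`, `n_replicates`, and the per-replicate
#'   accuracies in the `replicates` list-column. Rows are ordered by QTL
#'   scenario then panel (mp1 ... mp7).
#' @export
run_scenario <- function(panel_data, scenario, verbose = FALSE) {
  grid <- tidyr::expand_grid(n_qtl = scenario$n_qtl, h2 = scenario$h2)
  raw <- purrr::map_dfr(seq_len(nrow(grid)), function(ci) {
    nq <- grid$n_qtl[ci]; hh <- grid$h2[ci]
    arch0 <- if (!scenario$resample_qtl_per_replicate) {
      sample_architecture(panel_data, nq,
                          distribution = scenario$effect_distribution,
                          seed = replicate_seed(scenario$master_seed, nq, hh, 0L))
    } else NULL
    purrr::map_dfr(seq_len(scenario$n_replicates), function(r) {
      if (verbose) {
        message(sprintf("scenario n_qtl=%d h2=%.2f replicate %d/%d",
                        nq, hh, r, scenario$n_replicates))
      }
      run_replicate(panel_data, scenario, nq, hh, r, arch = arch0)
    })
  })
  aggregate_accuracy(raw)
}

aggregate_accuracy <- function(raw) {
  out <- raw |>
    dplyr::mutate(panel = factor(.data$panel, levels = paste0("mp", 1:7)),
                  model = factor(.data$model,
                                 levels = c("rrblup", "bayesB", "bayesC"))) |>
    dplyr::group_by(.data$n_qtl, .data$h2, .data$panel, .data$model) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      panel_size = round(mean(.data$panel_size)),
      mean_accuracy = mean(.data$accuracy),
      sd_accuracy = if (dplyr::n() > 1) stats::sd(.data$accuracy) else 0,
      mean_accuracy_y = mean(.data$accuracy_y),
      replicates = list(.data$accuracy),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$n_qtl, .data$h2, .data$panel, .data$model) |>
    dplyr::mutate(panel = as.character(.data$panel),
                  model = as.character(.data$model))
  structure(out, class = c("accuracy_table", class(out)))
}

#' Format one accuracy cell in the report style
#'
#' Mean to two decimals with the across-replicate SD in parentheses, e.g.
#' `"0.94 (0.01)"`. With a single replicate the SD is omitted. Rounding is
#' `sprintf`'s round-half-even on the stored doubles.
#'
#' @param mean,sd numeric scalars.
#' @param n_replicates replicate count; 1 drops the SD.
#' @return a string.
#' @export
format_accuracy_cell <- function(mean, sd, n_replicates = 2L) {
  if (n_replicates <= 1) return(sprintf("%.2f", mean))
  sprintf("%.2f (%.2f)", mean, sd)
}

#' Format an accuracy table as a text grid
#'
#' One block per (QTL scenario, heritability), rows mp1 ... mp7, columns
#' the fitted models, cells as [format_accuracy_cell()].
#'
#' @param tab an `accuracy_table` from [run_scenario()].
#' @return character vector of lines, invisibly printed with `cat()` by
#'   the caller.
#' @export
format_accuracy_table <- function(tab) {
  lines <- character(0)
  for (key in split(tab, interaction(tab$n_qtl, tab$h2, drop = TRUE))) {
    key <- dplyr::arrange(key, .data$panel, .data$model)
    lines <- c(lines, sprintf("QTL%d (h2 = %.1f)", key$n_qtl[1], key$h2[1]))
    wide <- key |>
      dplyr::mutate(cell = format_accuracy_cell(.data$mean_accuracy,
                                                .data$sd_accuracy,
                                                .data$n_replicates[1]),
                    label = sprintf("%s [%d loci]", .data$panel,
                                    .data$panel_size)) |>
      dplyr::select("label", "model", "cell") |>
      tidyr::pivot_wider(names_from = "model", values_from = "cell")
    lines <- c(lines, utils::capture.output(print(as.data.frame(wide),
                                                  row.names = FALSE)), "")
  }
  lines
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-replicate accuracies in long form
#'
#' @param x an `accuracy_table`.
#' @param ... unused.
#' @return a tibble with one row per (cell, panel, model, replicate).
#' @export
tidy.accuracy_table <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::select("n_qtl", "h2", "panel", "model", "replicates") |>
    dplyr::mutate(replicate = purrr::map(.data$replicates, seq_along)) |>
    tidyr::unnest(c("replicates", "replicate")) |>
    dplyr::rename(accuracy = "replicates") |>
    dplyr::relocate("replicate", .before = "accuracy")
}

#' One-row summary of an accuracy table
#'
#' @param x an `accuracy_table`.
#' @param ... unused.
#' @return a tibble with grid dimensions and the overall accuracy range.
#' @export
glance.accuracy_table <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x),
    n_qtl_levels = length(unique(x$n_qtl)),
    h2_levels = length(unique(x$h2)),
    n_panels = length(unique(x$panel)),
    n_models = length(unique(x$model)),
    min_accuracy = min(x$mean_accuracy),
    max_accuracy = max(x$mean_accuracy)
  )
}

#' Marker effects of a fitted whole-genome regression, tidied
#'
#' @param x a `wgr_fit`.
#' @param ... unused.
#' @return a tibble with `locus_id`, `effect` and, for the Bayes models,
#'   the posterior `inclusion_prob`.
#' @export
tidy.wgr_fit <- function(x, ...) {
  out <- tibble::tibble(locus_id = names(x$effects),
                        effect = unname(x$effects))
  if (!is.null(x$inclusion_prob)) {
    out$inclusion_prob <- unname(x$inclusion_prob)
  }
  out
}

#' One-row summary of a fitted whole-genome regression
#'
#' @param x a `wgr_fit`.
#' @param ... unused.
#' @return a one-row tibble of model label, intercept and variance
#'   components.
#' @export
glance.wgr_fit <- function(x, ...) {
  tibble::tibble(model = x$model, n_loci = length(x$effects),
                 intercept = x$intercept,
                 marker_variance = x$marker_variance,
                 residual_variance = x$residual_variance,
                 lambda = x$lambda, pi_zero = x$pi_zero)
}
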
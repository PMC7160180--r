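#' Pipeline configuration
#'
#' One object holding every tunable of the end-to-end analysis. The
#' `"genus"` preset keeps both exclusive and inclusive diversity contrasts
#' and weights gamma models by MCCR z-scores; the `"species"` preset
#' follows the reduced species-level design: hosts must be used by at
#' least five taxa, only inclusive contrasts are computed, and gamma
#' models are unweighted. Either toggle can be overridden explicitly.
#'
#' @param level `"genus"` or `"species"`.
#' @param min_host_users Hosts used by fewer taxa are removed.
#' @param breadth_cap Maximum host breadth B; over-breadth taxa dropped.
#' @param min_tips Minimum covered tips per analyzable clade.
#' @param max_states State-count cap per clade.
#' @param responses Contrast responses to compute.
#' @param mccr Weight gamma models by MCCR z-scores?
#' @param mccr_reps Null simulations per MCCR test.
#' @param mccr_variance Pass z-squared (a variance reading of the weight)
#'   instead of z into the measurement-error channel.
#' @param gamma_min_tips Minimum clade size for gamma statistics.
#' @param weighted Weight contrast regressions by event confidence?
#' @param n_starts DEC* optimizer restarts.
#' @param mixed_iter,mixed_thin,mixed_burnin Mixed-model MCMC settings
#'   (defaults are desk-scale; raise for production runs).
#' @param scale_gain,root_prior DEC* model options.
#' @param seed Master seed; every stochastic stage derives its own stream
#'   from it.
#' @return A list of class `hostshift_config`.
#' @export
pipeline_config <- function(level = c("genus", "species"),
                            min_host_users = if (level[1] == "species") 5L else 2L,
                            breadth_cap = 5L,
                            min_tips = 10L,
                            max_states = 1600L,
                            responses = if (level[1] == "species")
                              c("waiting_time", "inclusive") else
                              c("waiting_time", "exclusive", "inclusive"),
                            mccr = level[1] != "species",
                            mccr_reps = 100L,
                            mccr_variance = FALSE,
                            gamma_min_tips = 10L,
                            weighted = TRUE,
                            n_starts = 5L,
                            mixed_iter = 20000L, mixed_thin = 10L,
                            mixed_burnin = NULL,
                            scale_gain = TRUE, root_prior = "uniform",
                            seed = 1L) {
  level <- match.arg(level)
  structure(list(level = level, min_host_users = min_host_users,
                 breadth_cap = breadth_cap, min_tips = min_tips,
                 max_states = max_states, responses = responses,
                 mccr = mccr, mccr_reps = mccr_reps,
                 mccr_variance = mccr_variance,
                 gamma_min_tips = gamma_min_tips, weighted = weighted,
                 n_starts = n_starts, mixed_iter = mixed_iter,
                 mixed_thin = mixed_thin, mixed_burnin = mixed_burnin,
                 scale_gain = scale_gain, root_prior = root_prior,
                 seed = as.integer(seed)),
            class = "hostshift_config")
}

#' Run the full host-shift diversification analysis
#'
#' End-to-end orchestration: validate, filter hosts and breadth, decompose
#' the tree into analyzable clades, fit DEC* and reconstruct marginal
#' ancestral repertoires per clade, classify gains and losses, compute
#' sister-clade contrasts mapped back onto the complete tree, attach
#' ecological-opportunity indices to gain events, compute per-clade gamma
#' statistics with optional MCCR weights, and fit the contrast and gamma
#' models. Any stage failure aborts with a stage-tagged message; model
#' stages that are undetermined at desk scale (too few events) are
#' recorded as notes rather than errors.
#'
#' @param tree Complete phylogeny ([ape::phylo]).
#' @param hosts Named list mapping taxon to host vectors.
#' @param richness Optional named per-tip species counts (NULL = 1 each,
#'   the species-level convention).
#' @param host_meta Optional host metadata tibble for opportunity indices.
#' @param config A [pipeline_config()].
#' @return An object of class `hostshift_result`: list with `validation`,
#'   `decomposition`, `dec_fits`, `reconstructions`, `events`, `contrasts`,
#'   `indices`, `design`, `gammas`, `models` (list of fits), `notes`,
#'   `config`.
#' @export
run_pipeline <- function(tree, hosts, richness = NULL, host_meta = NULL,
                         config = pipeline_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("[", name, "] ", conditionMessage(e)))
    })
  }
  notes <- character(0)
  note <- function(msg) notes <<- c(notes, msg)

  validation <- stage("validate",
                      validate_dataset(tree, hosts, richness,
                                       breadth_cap = config$breadth_cap,
                                       min_host_users = config$min_host_users))

  filt <- stage("filter_hosts", filter_hosts(hosts, config$min_host_users))
  if (length(filt$dropped_hosts) > 0) {
    note(paste0("Hosts dropped (under ", config$min_host_users, " users): ",
                length(filt$dropped_hosts)))
  }
  capped <- stage("breadth_cap",
                  apply_breadth_cap(filt$hosts, config$breadth_cap))
  if (length(capped$dropped_taxa) > 0) {
    note(paste0("Over-breadth taxa dropped: ", length(capped$dropped_taxa)))
  }
  analysis_hosts <- capped$hosts

  decomp <- stage("decompose",
                  decompose_tree(tree, analysis_hosts,
                                 min_tips = config$min_tips,
                                 max_states = config$max_states,
                                 max_breadth = config$breadth_cap))
  if (length(decomp$subtrees) == 0) {
    abort("[decompose] No clade satisfies the size and state-space constraints.")
  }

  dec_fits <- list()
  recons <- list()
  events_list <- list()
  contrasts_list <- list()
  indices_list <- list()
  subs <- list()
  for (i in seq_along(decomp$subtrees)) {
    sub_full <- decomp$subtrees[[i]]
    covered <- intersect(sub_full$tip.label, names(analysis_hosts))
    sub <- if (length(covered) < ape::Ntip(sub_full)) {
      ape::keep.tip(sub_full, covered)
    } else sub_full
    local_hosts_all <- sort(unique(unlist(analysis_hosts[covered],
                                          use.names = FALSE)))
    b_eff <- min(config$breadth_cap, length(local_hosts_all))
    space <- host_state_space(local_hosts_all, b_eff)
    fit <- stage(paste0("dec_fit/subtree", i),
                 fit_dec(sub, analysis_hosts[covered], space,
                         n_starts = config$n_starts,
                         seed = config$seed + 100L + i,
                         scale_gain = config$scale_gain,
                         root_prior = config$root_prior))
    recon <- stage(paste0("marginals/subtree", i),
                   dec_ancestral_states(sub, analysis_hosts[covered], space,
                                        fit$d, fit$e,
                                        scale_gain = config$scale_gain,
                                        root_prior = config$root_prior))
    ev <- stage(paste0("events/subtree", i), classify_events(recon, sub))
    ctr <- stage(paste0("contrasts/subtree", i),
                 sister_contrasts(ev, sub, full_tree = tree,
                                  hosts = analysis_hosts,
                                  richness = richness,
                                  responses = config$responses))
    ev$subtree <- i
    ctr$subtree <- i
    dec_fits[[i]] <- fit
    recons[[i]] <- recon
    events_list[[i]] <- ev
    contrasts_list[[i]] <- ctr
    subs[[i]] <- sub
  }
  # Opportunity indices need the pooled event list (host volatility counts
  # gains across every subtree), so they come after the main loop.
  if (!is.null(host_meta)) {
    for (i in seq_along(decomp$subtrees)) {
      idx <- stage(paste0("opportunity/subtree", i),
                   opportunity_indices(events_list[[i]], subs[[i]], host_meta,
                                       all_events = events_list))
      if (nrow(idx) > 0) idx$subtree <- i
      indices_list[[i]] <- idx
    }
  }
  events <- dplyr::bind_rows(events_list)
  contrasts <- dplyr::bind_rows(contrasts_list)
  indices <- dplyr::bind_rows(indices_list)

  design <- NULL
  if (!is.null(host_meta) && nrow(indices) > 0) {
    design <- dplyr::bind_rows(lapply(seq_along(decomp$subtrees), function(i) {
      d <- assemble_design(contrasts_list[[i]], indices_list[[i]])
      if (nrow(d) > 0) d$subtree <- i
      d
    }))
  }

  models <- list()
  for (resp in config$responses) {
    models[[paste0("change_", resp)]] <- tryCatch(
      fit_change_model(contrasts, resp, weighted = config$weighted),
      error = function(e) {
        note(paste0("Change model (", resp, ") not fitted: ",
                    conditionMessage(e)))
        NULL
      })
    if (!is.null(design)) {
      models[[paste0("opportunity_", resp)]] <- tryCatch(
        fit_opportunity_model(design, resp, weighted = config$weighted),
        error = function(e) {
          note(paste0("Opportunity model (", resp, ") not fitted: ",
                      conditionMessage(e)))
          NULL
        })
    }
  }

  gammas <- NULL
  if (is_ultrametric_tree(tree)) {
    gammas <- stage("gamma",
                    clade_gammas_mccr(tree, min_tips = config$gamma_min_tips,
                                      richness = richness,
                                      mccr = config$mccr,
                                      reps = config$mccr_reps,
                                      seed = config$seed + 500L))
    if (nrow(gammas) > 0) {
      cls <- contrasts |>
        dplyr::distinct(.data$full_node, .data$class) |>
        dplyr::group_by(.data$full_node) |>
        dplyr::slice(1) |>
        dplyr::ungroup()
      gm <- dplyr::left_join(gammas, cls, by = c("node" = "full_node"))
      gm$class <- factor(ifelse(is.na(gm$class), "none", gm$class),
                         levels = c("gain", "loss", "none", "complex"))
      gm <- gm[gm$class != "complex", , drop = FALSE]
      gm$class <- droplevels(gm$class)
      gm$mev_col <- if (config$mccr && !anyNA(gm$z)) {
        if (config$mccr_variance) gm$z^2 else gm$z
      } else 0
      models$gamma_change <- tryCatch(
        phylo_mixed(gm, gamma ~ 0 + class, tree, node_col = "node",
                    mev = "mev_col",
                    n_iter = config$mixed_iter, thin = config$mixed_thin,
                    burnin = config$mixed_burnin %||%
                      floor(config$mixed_iter / 10),
                    seed = config$seed + 900L),
        error = function(e) {
          note(paste0("Gamma mixed model not fitted: ", conditionMessage(e)))
          NULL
        })
      gammas <- gm[, setdiff(names(gm), "mev_col")]
    }
  } else {
    note("Tree not ultrametric: gamma statistics skipped.")
  }

  structure(
    list(validation = validation, decomposition = decomp,
         dec_fits = dec_fits, reconstructions = recons, events = events,
         contrasts = contrasts, indices = indices, design = design,
         gammas = gammas, models = models, notes = notes, config = config),
    class = "hostshift_result"
  )
}

#' @export
print.hostshift_result <- function(x, ...) {
  cat("hostshift analysis (", x$config$level, " level)\n", sep = "")
  cat("  subtrees analyzed: ", length(x$decomposition$subtrees), "\n")
  cat("  events classified: ", nrow(x$events),
      " (", sum(x$events$class == "gain"), " gains, ",
      sum(x$events$class == "loss"), " losses)\n", sep = "")
  cat("  models fitted:     ",
      sum(!vapply(x$models, is.null, logical(1))), "\n")
  if (length(x$notes) > 0) cat("  notes:\n", paste0("   - ", x$notes, "\n"))
  invisible(x)
}

#' Coefficient summary table of a pipeline run
#'
#' One row per (model, term): the shape of a per-class coefficient table —
#' for the change models the terms are the gain/loss/none classes and the
#' coefficients are weighted class means of the contrasts.
#'
#' @param object A `hostshift_result`.
#' @param ... Unused.
#' @return A tibble: `model`, `term`, `estimate`, `p.value`.
#' @export
summary.hostshift_result <- function(object, ...) {
  rows <- list()
  for (nm in names(object$models)) {
    fit <- object$models[[nm]]
    if (is.null(fit)) next
    td <- tidy(fit)
    p <- if ("p.value" %in% names(td)) td$p.value else td$pMCMC
    rows[[length(rows) + 1]] <- tibble::tibble(
      model = nm, term = td$term, estimate = td$estimate, p.value = p)
  }
  if (length(rows) == 0) {
    return(tibble::tibble(model = character(0), term = character(0),
                          estimate = numeric(0), p.value = numeric(0)))
  }
  dplyr::bind_rows(rows)
}

#' Write all tabular outputs of a pipeline run
#'
#' Emits `events.tsv`, `contrasts.tsv`, `indices.tsv`, `gammas.tsv`,
#' `models.json` (coefficient tables plus configuration echo) and
#' `run.log` (notes and seeds).
#'
#' @param result A `hostshift_result`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_results <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(result$events, file.path(dir, "events.tsv"),
                   progress = FALSE)
  readr::write_tsv(result$contrasts, file.path(dir, "contrasts.tsv"),
                   progress = FALSE)
  if (nrow(result$indices %||% tibble::tibble()) > 0) {
    readr::write_tsv(result$indices, file.path(dir, "indices.tsv"),
                     progress = FALSE)
  }
  if (!is.null(result$gammas)) {
    readr::write_tsv(result$gammas, file.path(dir, "gammas.tsv"),
                     progress = FALSE)
  }
  model_json <- lapply(result$models, function(fit) {
    if (is.null(fit)) return(NULL)
    td <- tidy(fit)
    lapply(split(td, seq_len(nrow(td))), as.list)
  })
  jsonlite::write_json(list(models = model_json,
                            config = unclass(result$config),
                            notes = result$notes),
                       file.path(dir, "models.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  writeLines(c(paste0("seed: ", result$config$seed),
               paste0("level: ", result$config$level),
               result$notes),
             file.path(dir, "run.log"))
  invisible(dir)
}

#' Distribution of clade gamma statistics
#'
#' @param gammas Gamma table from a pipeline run or [clade_gammas_mccr()].
#' @return A ggplot object.
#' @export
plot_gamma_distribution <- function(gammas) {
  ggplot2::ggplot(gammas, ggplot2::aes(x = .data$gamma)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "red") +
    ggplot2::labs(x = expression(gamma), y = "clades") +
    ggplot2::theme_minimal()
}
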
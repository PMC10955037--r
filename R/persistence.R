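# Posterior persistence: a compressed columnar dump (parquet) plus a
# plain-text JSON manifest, so the validation stages can run without
# refitting.

encoder_to_list <- function(enc) {
  list(vars = enc$vars,
       columns = lapply(enc$columns, function(c)
         list(type = c$type, levels = c$levels)))
}

encoder_from_list <- function(lst) {
  structure(list(vars = unlist(lst$vars),
                 columns = lapply(lst$columns, function(c)
                   list(type = c$type, levels = unlist(c$levels)))),
            class = "bcf_encoder")
}

trees_to_table <- function(trees, forest) {
  purrr::map_dfr(seq_along(trees), function(d) {
    M <- trees[[d]]
    tibble::tibble(forest = forest, draw = d, row = seq_len(nrow(M)) - 1L,
                   tree = M[, 1], left = M[, 2], right = M[, 3],
                   var = M[, 4], cut = M[, 5], value = M[, 6])
  })
}

table_to_trees <- function(tab) {
  draws <- sort(unique(tab$draw))
  lapply(draws, function(d) {
    td <- tab[tab$draw == d, ]
    td <- td[order(td$row), ]
    as.matrix(td[, c("tree", "left", "right", "var", "cut", "value")])
  })
}

#' Persist and reload a fitted Bayesian causal forest
#'
#' Writes the retained posterior draws (per-individual prognostic and
#' treatment-effect values, noise SD, split counts and probabilities, sampled
#' ensembles) as parquet files under `dir`, together with a plain-text JSON
#' manifest recording dimensions, the outcome scaling, predictor encoders and
#' the sampler configuration. `read_bcf_posterior()` reconstructs a `bcf_fit`
#' equivalent for prediction and post-processing.
#'
#' @param fit A [fit_bcf()] result.
#' @param dir Output directory (created if needed).
#' @return `write_bcf_posterior()` returns `dir` invisibly;
#'   `read_bcf_posterior()` returns a `bcf_fit`.
#' @export
write_bcf_posterior <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  D <- ncol(fit$mu)
  surf <- tibble::tibble(
    draw = rep(seq_len(D), each = fit$n),
    row = rep(seq_len(fit$n), D),
    mu = as.numeric(fit$mu), tau = as.numeric(fit$tau))
  arrow::write_parquet(surf, file.path(dir, "surfaces.parquet"))
  arrow::write_parquet(
    tibble::tibble(draw = seq_len(D), sigma = fit$sigma,
                   tau_leaf_scale = fit$tau_leaf_scale,
                   depth_mu = fit$depth$mu, depth_tau = fit$depth$tau),
    file.path(dir, "scalars.parquet"))
  splits <- dplyr::bind_rows(lapply(c("mu", "tau"), function(f) {
    cnt <- fit$split_counts[[f]]
    tibble::tibble(forest = f, draw = rep(seq_len(nrow(cnt)), ncol(cnt)),
                   variable = rep(colnames(cnt), each = nrow(cnt)),
                   count = as.integer(cnt),
                   prob = as.numeric(fit$split_probs[[f]]))
  }))
  arrow::write_parquet(splits, file.path(dir, "splits.parquet"))
  if (length(fit$trees$mu) > 0) {
    arrow::write_parquet(
      dplyr::bind_rows(trees_to_table(fit$trees$mu, "mu"),
                       trees_to_table(fit$trees$tau, "tau")),
      file.path(dir, "trees.parquet"))
  }
  arrow::write_parquet(
    tibble::tibble(row = seq_len(fit$n), id = fit$id, z = fit$z, y = fit$y),
    file.path(dir, "rows.parquet"))
  cfg <- fit$config
  manifest <- list(
    package = "bcfselect", object = "bcf_fit",
    n = fit$n, n_draws = D,
    scale = fit$scale,
    sparsity = fit$sparsity,
    accept = fit$accept,
    bookkeeping_max_abs_err = fit$bookkeeping_max_abs_err,
    source_var = fit$source_var,
    encoder_mu = encoder_to_list(fit$encoder_mu),
    encoder_tau = encoder_to_list(fit$encoder_tau),
    config = cfg[!vapply(cfg, is.null, logical(1))])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_bcf_posterior
#' @export
read_bcf_posterior <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  n <- man$n; D <- man$n_draws
  surf <- arrow::read_parquet(file.path(dir, "surfaces.parquet"))
  surf <- surf[order(surf$draw, surf$row), ]
  scalars <- arrow::read_parquet(file.path(dir, "scalars.parquet"))
  splits <- arrow::read_parquet(file.path(dir, "splits.parquet"))
  rows <- arrow::read_parquet(file.path(dir, "rows.parquet"))
  unsplit <- function(f) {
    sp <- splits[splits$forest == f, ]
    vars <- unique(sp$variable)
    cnt <- matrix(sp$count, nrow = D, dimnames = list(NULL, vars))
    prob <- matrix(sp$prob, nrow = D, dimnames = list(NULL, vars))
    list(count = cnt, prob = prob)
  }
  smu <- unsplit("mu"); stau <- unsplit("tau")
  trees <- list(mu = list(), tau = list())
  tp <- file.path(dir, "trees.parquet")
  if (file.exists(tp)) {
    tt <- arrow::read_parquet(tp)
    trees <- list(mu = table_to_trees(tt[tt$forest == "mu", ]),
                  tau = table_to_trees(tt[tt$forest == "tau", ]))
  }
  cfg <- man$config
  class(cfg) <- "bcf_config"
  structure(list(
    mu = matrix(surf$mu, nrow = n),
    tau = matrix(surf$tau, nrow = n),
    sigma = scalars$sigma, tau_leaf_scale = scalars$tau_leaf_scale,
    split_counts = list(mu = smu$count, tau = stau$count),
    split_probs = list(mu = smu$prob, tau = stau$prob),
    depth = list(mu = scalars$depth_mu, tau = scalars$depth_tau),
    trees = trees,
    accept = man$accept,
    bookkeeping_max_abs_err = man$bookkeeping_max_abs_err,
    scale = man$scale,
    encoder_mu = encoder_from_list(man$encoder_mu),
    encoder_tau = encoder_from_list(man$encoder_tau),
    source_var = list(mu = unlist(man$source_var$mu),
                      tau = unlist(man$source_var$tau)),
    sparsity = man$sparsity, config = cfg,
    n = n, z = rows$z, y = rows$y, id = rows$id),
    class = "bcf_fit")
}
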
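#' Default caller pipeline configuration
#'
#' Returns the full default configuration block for
#' [run_caller_pipeline()]; write it to YAML to seed a reproducible run.
#'
#' @param expression Path to an expression TSV (or an in-memory
#'   [expression_matrix()]).
#' @param out_dir Output directory.
#' @param kind Expression unit in the file, `"raw"` or `"normalized"`.
#' @param signature_gmt Optional path to a two-set GMT (`*_UP`, `*_DOWN`);
#'   `NULL` uses the packaged NOTCH signature.
#' @param tau,normalize_scores,ktsp_threshold,ssgsea_threshold Caller
#'   parameters, see [caller_config()].
#' @param cluster_k Flat clusters for [signature_cluster()].
#' @param seed Integer seed recorded in the provenance of every output.
#' @return A named list.
#' @export
caller_pipeline_config <- function(expression, out_dir, kind = "raw",
                                   signature_gmt = NULL, tau = 0.25,
                                   normalize_scores = TRUE,
                                   ktsp_threshold = 0.5,
                                   ssgsea_threshold = NULL,
                                   cluster_k = 2L, seed = 1L) {
  list(expression = expression, out_dir = out_dir, kind = kind,
       signature_gmt = signature_gmt, tau = tau,
       normalize_scores = normalize_scores,
       ktsp_threshold = ktsp_threshold,
       ssgsea_threshold = ssgsea_threshold,
       cluster_k = cluster_k, seed = seed)
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML file path")
  config
}

config_hash <- function(config) {
  # stable content hash: md5 of the deparsed canonical form of the
  # analysis-relevant fields (the output location is not one of them)
  canon <- config[setdiff(names(config), "out_dir")]
  canon <- canon[!vapply(canon, function(x)
    is.matrix(x) || inherits(x, "data.frame"), logical(1))]
  canon <- canon[order(names(canon))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(canon), tmp)
  unname(tools::md5sum(tmp))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    abort("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

write_provenance <- function(path, config, extra = list()) {
  prov <- c(list(config_hash = config_hash(config),
                 seed = config$seed %||% NA_integer_),
            extra)
  jsonlite::write_json(prov, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
}

#' Run the NOTCH activation caller pipeline end to end
#'
#' Stages, in order: read (or accept) the expression matrix; normalize
#' raw counts by median-of-ratios; score and call activation
#' ([notch_call()]); cluster samples on signature genes
#' ([signature_cluster()]). All tabular outputs plus a provenance record
#' (config hash, seed, row counts per stage) are written to
#' `config$out_dir`; identical config and seed yield byte-identical
#' outputs.
#'
#' @param config A list (see [caller_pipeline_config()]) or a YAML path.
#' @return Invisibly, a list with `normalized`, `call`
#'   (the `notch_call` object), `clustering` and `out_dir`.
#' @export
run_caller_pipeline <- function(config) {
  config <- load_config(config)
  if (is.null(config$out_dir)) abort("config needs `out_dir`")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  expr <- run_stage("read_expression", {
    if (inherits(config$expression, "expr_matrix")) config$expression
    else read_expression_matrix(config$expression,
                                kind = config$kind %||% "raw")
  })
  signature <- run_stage("read_signature", {
    if (is.null(config$signature_gmt)) notch_signature()
    else {
      sets <- read_gmt(config$signature_gmt)
      names(sets) <- vapply(sets, `[[`, "", "name")
      up <- grep("_UP$", names(sets), value = TRUE)
      down <- grep("_DOWN$", names(sets), value = TRUE)
      if (length(up) != 1L || length(down) != 1L)
        abort("signature GMT must contain exactly one *_UP and one *_DOWN set")
      gene_signature(sets[[up]]$genes, sets[[down]]$genes,
                     name = sub("_UP$", "", up))
    }
  })
  normalized <- run_stage("normalize", {
    if (expr_kind(expr) == "raw") normalize_counts(expr) else expr
  })
  fit <- run_stage("call_activation", {
    cfg <- caller_config(tau = config$tau %||% 0.25,
                         normalize_scores = config$normalize_scores %||% TRUE,
                         ktsp_threshold = config$ktsp_threshold %||% 0.5,
                         ssgsea_threshold = config$ssgsea_threshold)
    notch_call(normalized, signature, cfg)
  })
  clustering <- run_stage("signature_cluster", {
    signature_cluster(normalized, signature, k = config$cluster_k %||% 2L)
  })

  run_stage("write_outputs", {
    write_expression_matrix(normalized,
                            file.path(config$out_dir, "normalized_matrix.tsv"))
    write_results(fit$scores,
                  file.path(config$out_dir, "activation_calls.tsv"), "tsv")
    ord <- clustering$hclust$order
    sig_mat <- unclass(normalized)[clustering$genes_used, ord, drop = FALSE]
    write_expression_matrix(expression_matrix(sig_mat, "normalized"),
                            file.path(config$out_dir,
                                      "signature_matrix_clustered.tsv"))
    write_results(data.frame(sample_id = names(clustering$labels),
                             cluster = unname(clustering$labels),
                             stringsAsFactors = FALSE),
                  file.path(config$out_dir, "cluster_labels.tsv"), "tsv")
    write_provenance(file.path(config$out_dir, "provenance.json"), config,
                     list(n_genes = nrow(normalized),
                          n_samples = ncol(normalized),
                          n_activated = sum(fit$scores$call == "activated"),
                          thresholds = as.list(fit$thresholds)))
  })
  invisible(list(normalized = normalized, call = fit,
                 clustering = clustering, out_dir = config$out_dir))
}

#' Run the xenograft efficacy pipeline end to end
#'
#' Stages: read (or accept) the growth table; compute caliper volumes
#' where absent; %TGI of every treated group against the control; per
#' animal ln-volume regression slopes; ANOVA with Tukey-Kramer pairwise
#' comparisons across groups. Outputs and a provenance record are written
#' to `config$out_dir`.
#'
#' @param config List or YAML path with fields `growth` (CSV path or
#'   `growth_table`), `control_group`, optional `treated_groups`
#'   (default: all non-control groups), `baseline_day`, `final_day`,
#'   `summary` (`"mean"`/`"median"`), `out_dir`, `seed`.
#' @return Invisibly, a list with `volumes`, `tgi` (data frame),
#'   `slopes`, `comparison`, `out_dir`.
#' @export
run_efficacy_pipeline <- function(config) {
  config <- load_config(config)
  if (is.null(config$out_dir)) abort("config needs `out_dir`")
  if (is.null(config$control_group)) abort("config needs `control_group`")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  growth <- run_stage("read_growth", {
    if (inherits(config$growth, "growth_table")) config$growth
    else read_growth_table(config$growth)
  })
  growth <- run_stage("compute_volumes", ensure_volume(growth))
  treated <- config$treated_groups %||%
    setdiff(unique(growth$group), config$control_group)
  tgi <- run_stage("percent_tgi", {
    rows <- lapply(treated, function(grp) {
      r <- percent_tgi(growth, grp, config$control_group,
                       baseline_day = config$baseline_day,
                       final_day = config$final_day,
                       summary = config$summary %||% "mean")
      data.frame(treated_group = grp, control_group = config$control_group,
                 baseline_day = r$baseline_day, final_day = r$final_day,
                 baseline_mean_t = r$baseline_mean_t,
                 final_mean_t = r$final_mean_t,
                 baseline_mean_c = r$baseline_mean_c,
                 final_mean_c = r$final_mean_c,
                 tgi_percent = r$tgi_percent, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  slopes <- run_stage("growth_slopes", growth_slopes(growth))
  comparison <- run_stage("anova_tukey", anova_tukey(slopes))

  run_stage("write_outputs", {
    write_results(as.data.frame(growth),
                  file.path(config$out_dir, "volumes.tsv"), "tsv")
    write_results(tgi, file.path(config$out_dir, "tgi.tsv"), "tsv")
    write_results(as.data.frame(slopes),
                  file.path(config$out_dir, "slopes.tsv"), "tsv")
    write_results(comparison$pairwise,
                  file.path(config$out_dir, "comparisons.tsv"), "tsv")
    write_provenance(file.path(config$out_dir, "provenance.json"), config,
                     list(n_rows = nrow(growth),
                          n_animals = length(unique(growth$animal_id)),
                          anova_F = comparison$anova_F,
                          anova_p = comparison$anova_p))
  })
  invisible(list(volumes = growth, tgi = tgi, slopes = slopes,
                 comparison = comparison, out_dir = config$out_dir))
}
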
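# Readers and writers for the tabular interchange formats: TSV networks and
# evidence, CSV posterior summaries, JSON run logs, YAML configuration.

#' Read a signed TF-gene network
#'
#' Accepts either a TSV file with header columns `tf`, `gene` and `sign` (or
#' `mode`; sign tokens `A`/`I`, `activation`/`inhibition`, `+1`/`-1`), or a
#' JSON adjacency object mapping each TF to an object of `gene: sign` pairs.
#' Duplicate edges are collapsed with a warning; unknown sign tokens raise a
#' parse error naming the offending line.
#'
#' @param path file path; `.json` selects the JSON reader.
#' @return A [causal_graph()].
#' @export
read_network <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    adj <- jsonlite::read_json(path)
    tf <- rep(names(adj), lengths(adj))
    gene <- unlist(lapply(adj, names), use.names = FALSE)
    mode <- unlist(adj, use.names = FALSE)
    return(causal_graph(tf, gene, mode))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  names(tab) <- tolower(names(tab))
  if (!is.null(tab$mode) && is.null(tab$sign)) tab$sign <- tab$mode
  need <- c("tf", "gene", "sign")
  if (!all(need %in% names(tab)))
    stop(sprintf("network file must have columns %s",
                 paste(need, collapse = ", ")))
  probe <- vapply(tab$sign, function(s)
    tryCatch({ normalize_mode(s); TRUE }, error = function(e) FALSE),
    logical(1), USE.NAMES = FALSE)
  if (!all(probe))
    stop(sprintf("unknown sign token %s at line %d of %s",
                 sQuote(tab$sign[which(!probe)[1]]), which(!probe)[1] + 1L,
                 path))
  causal_graph(tab$tf, tab$gene, tab$sign)
}

#' Write a network as TSV
#' @param graph a [causal_graph()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network <- function(graph, path) {
  stopifnot(inherits(graph, "causal_graph"))
  e <- graph$edges
  utils::write.table(data.frame(tf = e$tf, gene = e$gene, sign = e$mode),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene-expression evidence
#'
#' Auto-detects the file layout from the header: a two-column table
#' (`gene`, `value`) is taken as pre-discretized evidence in -1/0/+1, while a
#' DEG table (gene, log2 fold-change, p-value, optional adjusted p-value) is
#' discretized with [discretize_deg()] using the thresholds supplied here.
#'
#' @param path TSV file path.
#' @param p_cutoff,fc_cutoff,top_n discretization thresholds, used only for
#'   DEG tables; see [discretize_deg()].
#' @return Named evidence vector.
#' @export
read_evidence <- function(path, p_cutoff = 0.01, fc_cutoff = 1, top_n = 800) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  low <- tolower(names(tab))
  if (all(c("gene", "value") %in% low)) {
    v <- validate_evidence(stats::setNames(as.numeric(tab[[which(low == "value")[1]]]),
                                           as.character(tab[[which(low == "gene")[1]]])))
    return(v)
  }
  discretize_deg(tab, p_cutoff = p_cutoff, fc_cutoff = fc_cutoff, top_n = top_n)
}

#' Write discretized evidence as TSV
#' @param evidence named evidence vector.
#' @param path output file.
#' @param drop_zero omit unchanged genes (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_evidence <- function(evidence, path, drop_zero = FALSE) {
  evidence <- validate_evidence(evidence)
  if (drop_zero) evidence <- evidence[evidence != 0]
  utils::write.table(data.frame(gene = names(evidence), value = evidence),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the ranked posterior summary as CSV
#'
#' Columns: `tf`, `posterior`, `tier`, `n_targets`, `n_de_targets`,
#' `fisher_p`, `mean_theta`.
#'
#' @param fit an [ornor()] fit (or an existing [summary.ornor()] object).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_posterior <- function(fit, path) {
  s <- if (inherits(fit, "summary.ornor")) fit else summary(fit)
  utils::write.csv(s$tf, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a machine-readable run log
#'
#' Records everything needed to reproduce and audit a fit: package version,
#' seed, problem dimensions, resolved hyper-parameters, sampler settings,
#' iteration count, convergence flag and the final maximum Gelman-Rubin
#' statistic, as JSON.
#'
#' @param fit an [ornor()] fit.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(fit, path) {
  stopifnot(inherits(fit, "ornor"))
  h <- fit$hyper
  log <- list(
    package = "ornor",
    version = as.character(utils::packageVersion("ornor")),
    seed = fit$seed,
    n_tf = nrow(fit$tf), n_gene = nrow(fit$genes), n_edge = nrow(fit$edges),
    n_de = sum(fit$evidence != 0),
    n_dropped_evidence = fit$n_dropped_evidence,
    hyper = list(zeta_deg = h$zeta_deg, zeta_nondeg = h$zeta_nondeg,
                 q = h$q, p0 = h$p0, theta_a = h$theta_a, theta_b = h$theta_b,
                 s_prior = c(h$s_prior_conf, h$s_prior_na, h$s_prior_opp),
                 obs = as.vector(h$obs)),
    control = unclass(fit$control),
    iterations = fit$iterations,
    converged = fit$converged,
    max_gelman_rubin = fit$max_r,
    elapsed_seconds = fit$elapsed)
  jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a YAML configuration file
#'
#' Returns hyper-parameter, sampler and simulation settings from a YAML file
#' with optional top-level sections `hyper`, `control` and `simulation`,
#' merged over the package defaults. Used by the command-line interface
#' (`inst/cli/ornor-cli.R`); fields mirror the arguments of [ornor_hyper()],
#' [ornor_control()], [sim_network()] and [sim_evidence()].
#'
#' @param path YAML file path.
#' @return List with elements `hyper` (class `ornor_hyper`), `control`
#'   (class `ornor_control`) and `simulation` (plain list).
#' @export
read_config <- function(path) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  hy <- do.call(ornor_hyper, cfg$hyper %||% list())
  ct <- do.call(ornor_control, cfg$control %||% list())
  list(hyper = hy, control = ct, simulation = cfg$simulation %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
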
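#' Signed TF-gene causal graph
#'
#' Constructs the prior regulatory network used for inference: a bipartite
#' directed graph from transcription factors (TFs) to target genes, in which
#' every edge carries a curated mode of regulation, activation (`"A"`) or
#' inhibition (`"I"`). TF and gene identifiers live in separate node layers, so
#' an identifier may legally appear on both sides (a TF regulating its own
#' gene); the graph is acyclic by construction.
#'
#' Duplicate `(tf, gene)` pairs are collapsed to their first occurrence with a
#' warning. The optional `tf_ids`/`gene_ids` arguments declare a node universe
#' larger than the set touched by edges (useful after perturbations that may
#' strip all edges from a gene); by default the universe is taken from the
#' edges themselves.
#'
#' @param tf character vector of TF identifiers, one per edge.
#' @param gene character vector of target-gene identifiers, one per edge.
#' @param mode per-edge regulation mode. Accepted encodings: `"A"`/`"I"`,
#'   `"activation"`/`"inhibition"`, `"+1"`/`"-1"`, or numeric `1`/`-1`.
#' @param tf_ids,gene_ids optional explicit node universes (character).
#' @return An object of class `"causal_graph"`: a list with elements `edges`
#'   (data frame with columns `tf`, `gene`, `mode`), `tf_ids` and `gene_ids`.
#' @examples
#' g <- causal_graph(tf   = c("T1", "T1", "T2"),
#'                   gene = c("g1", "g2", "g2"),
#'                   mode = c("A", "I", "A"))
#' g
#' @seealso [read_network()], [sim_network()], [ornor()]
#' @export
causal_graph <- function(tf, gene, mode, tf_ids = NULL, gene_ids = NULL) {
  tf <- as.character(tf)
  gene <- as.character(gene)
  mode <- normalize_mode(mode)
  if (length(tf) != length(gene) || length(gene) != length(mode))
    stop("'tf', 'gene' and 'mode' must have equal length")
  if (length(tf) == 0L)
    stop("causal graph must contain at least one edge")
  if (anyNA(tf) || anyNA(gene) || !all(nzchar(tf)) || !all(nzchar(gene)))
    stop("missing or empty identifiers in edge list")

  key <- paste(tf, gene, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- duplicated(key)
    warning(sprintf("collapsed %d duplicate (tf, gene) edge(s); kept first occurrence",
                    sum(dup)))
    tf <- tf[!dup]; gene <- gene[!dup]; mode <- mode[!dup]
  }

  tf_ids <- if (is.null(tf_ids)) sort(unique(tf)) else as.character(tf_ids)
  gene_ids <- if (is.null(gene_ids)) sort(unique(gene)) else as.character(gene_ids)
  if (!all(tf %in% tf_ids)) stop("edge references a TF absent from 'tf_ids'")
  if (!all(gene %in% gene_ids)) stop("edge references a gene absent from 'gene_ids'")

  structure(list(edges = data.frame(tf = tf, gene = gene, mode = mode,
                                    stringsAsFactors = FALSE),
                 tf_ids = tf_ids, gene_ids = gene_ids),
            class = "causal_graph")
}

# Map the accepted mode encodings onto "A"/"I" ("N" is the latent
# not-applicable state and is only legal inside model states, not annotations).
normalize_mode <- function(mode, allow_na_mode = FALSE) {
  m <- toupper(trimws(as.character(mode)))
  out <- ifelse(m %in% c("A", "ACTIVATION", "+", "+1", "1"), "A",
         ifelse(m %in% c("I", "INHIBITION", "REPRESSION", "-", "-1"), "I",
         ifelse(allow_na_mode & m %in% c("N", "NA", "0"), "N", NA_character_)))
  if (anyNA(out)) {
    bad <- unique(m[is.na(out)])
    stop(sprintf("unknown regulation mode token(s): %s",
                 paste(sQuote(bad), collapse = ", ")))
  }
  out
}

#' @export
print.causal_graph <- function(x, ...) {
  e <- x$edges
  cat(sprintf("Causal TF->gene graph: %d TFs, %d genes, %d edges (%.1f%% activation)\n",
              length(x$tf_ids), length(x$gene_ids), nrow(e),
              100 * mean(e$mode == "A")))
  deg <- table(factor(e$tf, levels = x$tf_ids))
  cat(sprintf("Targets per TF: median %d, range %d-%d\n",
              as.integer(stats::median(deg)), min(deg), max(deg)))
  invisible(x)
}

#' @export
as.data.frame.causal_graph <- function(x, ...) x$edges

#' Number of edges in a causal graph
#' @param graph a [causal_graph()].
#' @return Integer edge count.
#' @export
n_edges <- function(graph) {
  stopifnot(inherits(graph, "causal_graph"))
  nrow(graph$edges)
}

# Per-TF out-degree over the declared TF universe.
tf_degree <- function(graph) {
  tab <- table(factor(graph$edges$tf, levels = graph$tf_ids))
  stats::setNames(as.integer(tab), graph$tf_ids)
}
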
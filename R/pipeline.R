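# End-to-end orchestration: expression scoring -> binding scoring ->
# Pareto ranking of both edge types -> per-circRNA annotation ->
# ranking-method evaluation, with run-metadata stamping and deterministic
# re-runs.

#' Default pipeline configuration
#'
#' @return Named list of default thresholds and options; see
#'   [run_pipeline()] for their meaning.
#' @export
default_config <- function() {
  list(
    min_total_count = 10,
    min_mean_norm = 10,
    circular = TRUE,
    min_site_type = "6mer",
    mirna_mode = "top_score",
    top_score = 0.95,
    top_n = 10L,
    n_perm = 10000L,
    alpha = 0.05,
    n_max = 60L,
    annotate_circs = NULL,
    seed = NULL)
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cfg <- utils::modifyList(default_config(), config)
  if (is.null(cfg$seed) && cfg$n_perm > 0)
    stop("run_pipeline: a seed is required whenever permutations are run")
  cfg
}

#' Assemble the circRNA-miRNA interaction table
#'
#' Joins the pan-tissue co-expression score with the length-normalized
#' binding score on the union of pairs; a score missing for a pair (not
#' co-expressed, or no seed site) enters as 0, consistent with "no
#' evidence".
#'
#' @param coexpr [interaction_table()] with criterion `S_exp` from
#'   [coexpression_score()].
#' @param binding `binding_score_table` from [binding_score()].
#' @return An [interaction_table()] with criteria `S_exp` and `mre_per_kb`
#'   plus an `n_mre` column carried along for evaluation.
#' @export
build_circ_mir_table <- function(coexpr, binding) {
  a <- data.frame(source_id = coexpr$source_id, target_id = coexpr$target_id,
                  S_exp = coexpr$S_exp, stringsAsFactors = FALSE)
  b <- data.frame(source_id = binding$circ_id, target_id = binding$mir_id,
                  n_mre = binding$n_mre, mre_per_kb = binding$mre_per_kb,
                  stringsAsFactors = FALSE)
  m <- merge(a, b, by = c("source_id", "target_id"), all = TRUE)
  m$S_exp[is.na(m$S_exp)] <- 0
  m$n_mre[is.na(m$n_mre)] <- 0L
  m$mre_per_kb[is.na(m$mre_per_kb)] <- 0
  out <- interaction_table(m$source_id, m$target_id,
                           criteria = list(S_exp = m$S_exp,
                                           mre_per_kb = m$mre_per_kb),
                           edge_type = "circ-mir")
  out$n_mre <- m$n_mre
  out
}

#' Assemble the miRNA-gene interaction table
#'
#' @param evidence `mir_gene_evidence` from [load_mir_gene_evidence()].
#' @return An [interaction_table()] with criteria `n_mre_targetscan` and
#'   `n_pubs_mirtarbase`.
#' @export
build_mir_gene_table <- function(evidence) {
  interaction_table(evidence$mir_id, evidence$gene_id,
                    criteria = list(n_mre_targetscan = evidence$n_mre_targetscan,
                                    n_pubs_mirtarbase = evidence$n_pubs_mirtarbase),
                    edge_type = "mir-gene")
}

#' Run the full ceRNA prioritization and annotation pipeline
#'
#' Stages, in order: tissue ECDF scores for the circRNA and miRNA panels;
#' pan-tissue co-expression scores; seed-site counting on circRNA mature
#' sequences and length normalization; Pareto ranking of circRNA-miRNA
#' edges on (co-expression, MREs/kb) and of miRNA-gene edges on
#' (TargetScan MRE count, miRTarBase publication count); per-circRNA
#' annotation (permutation gene p-values and Fisher set enrichment); and,
#' when a reference list is given, a precision/recall comparison of the
#' Pareto, raw-MRE and MREs/kb rankings.
#'
#' Identical config and inputs reproduce identical outputs, including
#' permutation p-values; every output table is stamped with the package
#' version, the parameters and the seed. On any stage failure, partial
#' outputs are removed.
#'
#' @param inputs Either a `fixture_bundle` from [generate_fixtures()] or a
#'   named list of paths: `circ_expr`, `mir_expr`, `circ_seqs`,
#'   `mir_seqs`, `targetscan`, `mirtarbase`, `gene_sets`, and optionally
#'   `reference`.
#' @param config Named list (or YAML file path) overriding
#'   [default_config()]: `circular`, `min_site_type`, `mirna_mode`
#'   (`"all"`, `"top_score"`, `"top_n"`), `top_score`, `top_n`, `n_perm`,
#'   `alpha`, `n_max`, `annotate_circs` (circRNA ids to annotate; default
#'   the reference list if present) and `seed` (mandatory when
#'   `n_perm > 0`).
#' @param out_dir Optional output directory; when given, all result tables
#'   are written there as TSV.
#' @return A list with elements `circ_mir` (scored ranking), `mir_gene`
#'   (scored ranking), `annotations` (named list per annotated circRNA,
#'   see [annotate_circrna()]), `comparison` (precision/recall table or
#'   `NULL`) and `config`.
#' @export
run_pipeline <- function(inputs, config = list(), out_dir = NULL) {
  cfg <- read_run_config(config)

  if (inherits(inputs, "fixture_bundle")) {
    bundle <- inputs
  } else {
    stopifnot(is.list(inputs))
    need <- c("circ_expr", "mir_expr", "circ_seqs", "mir_seqs",
              "targetscan", "mirtarbase", "gene_sets")
    missing_keys <- setdiff(need, names(inputs))
    if (length(missing_keys))
      stop("run_pipeline: missing inputs: ", paste(missing_keys, collapse = ", "))
    paths <- unlist(inputs[c(need, intersect("reference", names(inputs)))])
    absent <- paths[!file.exists(paths)]
    if (length(absent))
      stop("run_pipeline: input file(s) not found: ",
           paste(absent, collapse = ", "))
    bundle <- list(
      circ_expr = read_expression_tsv(inputs$circ_expr, "circRNA", "SRPBM"),
      mir_expr = read_expression_tsv(inputs$mir_expr, "miRNA", "CPM"),
      circ_seqs = read_fasta(inputs$circ_seqs),
      mir_seqs = read_fasta(inputs$mir_seqs),
      targetscan = inputs$targetscan,
      mirtarbase = inputs$mirtarbase,
      gene_sets = read_gmt(inputs$gene_sets),
      reference = if (!is.null(inputs$reference))
        readLines(inputs$reference, warn = FALSE) else NULL)
  }

  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    stop(e)
  }
  tryCatch({
    # expression evidence
    circ_scores <- tissue_ecdf_scores(bundle$circ_expr)
    mir_scores <- tissue_ecdf_scores(bundle$mir_expr)
    coexpr <- coexpression_score(circ_scores, mir_scores)

    # binding evidence
    site_counts <- count_seed_sites(bundle$circ_seqs, bundle$mir_seqs,
                                    circular = cfg$circular,
                                    min_site_type = cfg$min_site_type)
    binding <- binding_score(site_counts, nchar(bundle$circ_seqs))

    # Pareto integration, both edge types
    circ_mir <- pareto_rank(build_circ_mir_table(coexpr, binding))
    evidence <- load_mir_gene_evidence(bundle$targetscan, bundle$mirtarbase)
    mir_gene <- pareto_rank(build_mir_gene_table(evidence))

    # per-circRNA annotation
    circs <- cfg$annotate_circs
    if (is.null(circs)) circs <- bundle$reference
    annotations <- list()
    if (length(circs)) {
      annotations <- lapply(circs, function(cc)
        annotate_circrna(cc, circ_mir, mir_gene, bundle$gene_sets,
                         mode = cfg$mirna_mode, top_score = cfg$top_score,
                         top_n = cfg$top_n, n_perm = cfg$n_perm,
                         seed = cfg$seed, alpha = cfg$alpha))
      names(annotations) <- circs
    }

    # ranking-method comparison against the reference list
    comparison <- NULL
    if (length(bundle$reference)) {
      rankings <- list(pareto = rank_edges(circ_mir, "pareto"),
                       nMRE = rank_edges(circ_mir, "nMRE"),
                       nMRE_per_kb = rank_edges(circ_mir, "nMRE_per_kb"))
      comparison <- precision_recall_curves(rankings, bundle$reference,
                                            n_max = cfg$n_max)
    }

    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      stamp <- cfg[c("circular", "min_site_type", "mirna_mode", "top_score",
                     "top_n", "n_perm", "alpha", "n_max", "seed")]
      w <- function(df, name) {
        p <- file.path(out_dir, name)
        written <<- c(written, p)
        write_result_tsv(df, p, params = stamp)
      }
      w(as.data.frame(circ_mir), "circ_mir_ranking.tsv")
      w(as.data.frame(mir_gene), "mir_gene_ranking.tsv")
      for (cc in names(annotations)) {
        w(annotations[[cc]]$genes, paste0("genes_", cc, ".tsv"))
        if (!is.null(annotations[[cc]]$enrichment))
          w(annotations[[cc]]$enrichment, paste0("enrichment_", cc, ".tsv"))
      }
      if (!is.null(comparison)) w(comparison, "ranking_comparison.tsv")
    }

    list(circ_mir = circ_mir, mir_gene = mir_gene,
         annotations = annotations, comparison = comparison, config = cfg)
  }, error = on_fail)
}
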
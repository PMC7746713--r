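# Self-contained synthetic input bundles with configurable planted sponge
# signal. The generator emulates the statistical structure the method
# assumes -- tissue-specific co-expression plus seed-site abundance driving
# true ceRNA edges -- so that every stage and the end-to-end pipeline are
# testable without any external download.

#' Configuration for the synthetic fixture generator
#'
#' Background expression is i.i.d. log-normal per feature-tissue with a
#' per-tissue dropout probability (a feature is simply unexpressed in some
#' tissues, as circRNAs are in real panels). Planted sponge circRNAs are
#' raised to a target expression quantile in one tissue shared with their
#' planted miRNAs, their mature sequences are seeded with exact 8mer sites
#' for those miRNAs at a set density, and the planted miRNAs receive
#' elevated MRE/publication evidence against one designated target gene
#' set.
#'
#' @param n_tissues,n_circ,n_mir,n_gene,n_sets Universe sizes.
#' @param planted A list of plant descriptors, each a list with elements
#'   `circ_id`, `mir_ids`, `target_set`, `coexpression_strength` (target
#'   ECDF quantile in `[0,1]`; 1 places the pair at the tied maximum of its
#'   tissue) and `sites_per_kb` (planted seed-site density on the circRNA).
#'   Default: three sponge circRNAs with three miRNAs each at strength 1
#'   and 2 sites/kb.
#' @param noise Log-normal dispersion (sdlog) of background expression.
#' @param p_expressed Probability a background feature is expressed in a
#'   given tissue.
#' @param circ_length_range Range of circRNA mature-sequence lengths (nt);
#'   background lengths are log-uniform over it, planted circRNAs sit at
#'   the low end so that raw site counts stay length-confounded for the
#'   background only.
#' @param seed Mandatory random seed.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(n_tissues = 5L, n_circ = 200L, n_mir = 30L,
                           n_gene = 300L, n_sets = 10L, planted = NULL,
                           noise = 1.0, p_expressed = 0.7,
                           circ_length_range = c(300L, 3000L), seed) {
  if (missing(seed) || is.null(seed)) stop("fixture_config: seed is mandatory")
  circ_ids <- sprintf("circ%03d", seq_len(n_circ))
  mir_ids <- sprintf("miR-%02d", seq_len(n_mir))
  set_names <- sprintf("SET%02d", seq_len(n_sets))
  if (is.null(planted)) {
    planted <- lapply(1:3, function(i) {
      list(circ_id = circ_ids[i],
           mir_ids = mir_ids[(i - 1L) * 3L + 1:3],
           target_set = set_names[i],
           coexpression_strength = 1.0,
           sites_per_kb = 2.0)
    })
  }
  for (p in planted) {
    stopifnot(p$circ_id %in% circ_ids, all(p$mir_ids %in% mir_ids),
              p$target_set %in% set_names,
              p$coexpression_strength >= 0, p$coexpression_strength <= 1,
              p$sites_per_kb >= 0)
  }
  structure(list(n_tissues = n_tissues, n_circ = n_circ, n_mir = n_mir,
                 n_gene = n_gene, n_sets = n_sets, planted = planted,
                 noise = noise, p_expressed = p_expressed,
                 circ_length_range = circ_length_range, seed = seed),
            class = "fixture_config")
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# the 8-nt target-side site fully complementary to miRNA positions 2-8,
# followed by the A1 anchor: [m8 match][seed match][A]
planted_site_seq <- function(mirna) {
  paste0(rna_revcomp(substr(mirna, 2L, 8L)), "A")
}

#' Generate a synthetic input bundle
#'
#' @param config A [fixture_config()].
#' @return A list of class `fixture_bundle` with elements `circ_expr` and
#'   `mir_expr` ([expression_panel()]s of per-tissue mean normalized
#'   expression), `circ_seqs` and `mir_seqs` ([sequence_set()]s),
#'   `targetscan` and `mirtarbase` (miRNA-gene evidence data.frames),
#'   `gene_sets` (a [gene_set_collection()]), `reference` (character
#'   vector of planted circRNA ids) and `config`. Byte-identical across
#'   calls with the same config.
#' @export
generate_fixtures <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  tissues <- sprintf("tissue%02d", seq_len(config$n_tissues))
  circ_ids <- sprintf("circ%03d", seq_len(config$n_circ))
  mir_ids <- sprintf("miR-%02d", seq_len(config$n_mir))
  gene_ids <- sprintf("G%04d", seq_len(config$n_gene))
  set_names <- sprintf("SET%02d", seq_len(config$n_sets))

  draw_panel <- function(ids, meanlog) {
    v <- matrix(stats::rlnorm(length(ids) * length(tissues), meanlog,
                              config$noise),
                length(ids), length(tissues),
                dimnames = list(ids, tissues))
    drop_mask <- matrix(stats::runif(length(v)) > config$p_expressed,
                        nrow(v), ncol(v))
    v[drop_mask] <- 0
    # keep every tissue scorable
    for (j in seq_len(ncol(v)))
      if (all(v[, j] == 0)) v[1L, j] <- stats::rlnorm(1L, meanlog, config$noise)
    v
  }
  circ_v <- draw_panel(circ_ids, meanlog = 2)
  mir_v <- draw_panel(mir_ids, meanlog = 4)

  # planted co-expression: one shared tissue per plant, both partners
  # raised to the strength quantile of that tissue's expressed values
  plant_tissue <- setNames(
    tissues[(seq_along(config$planted) - 1L) %% length(tissues) + 1L],
    vapply(config$planted, `[[`, character(1), "circ_id"))
  boost <- function(v, id, tissue, strength) {
    col <- v[, tissue]
    pool <- col[col > 0]
    v[id, tissue] <- stats::quantile(pool, probs = strength, type = 7, names = FALSE)
    v
  }
  for (p in config$planted) {
    tt <- plant_tissue[[p$circ_id]]
    circ_v <- boost(circ_v, p$circ_id, tt, p$coexpression_strength)
    for (m in p$mir_ids) mir_v <- boost(mir_v, m, tt, p$coexpression_strength)
  }

  # sequences: miRNAs 22 nt; circRNA lengths log-uniform over the range,
  # planted circRNAs at the low end of the range
  mir_seq_v <- setNames(vapply(mir_ids, function(i) random_seq(22L),
                               character(1)), mir_ids)
  lr <- log(config$circ_length_range)
  circ_len <- setNames(as.integer(round(exp(stats::runif(config$n_circ,
                                                         lr[1L], lr[2L])))),
                       circ_ids)
  planted_circ <- vapply(config$planted, `[[`, character(1), "circ_id")
  circ_len[planted_circ] <- as.integer(round(
    config$circ_length_range[1L] * 1.5))
  circ_seq_v <- setNames(vapply(circ_len, random_seq, character(1)), circ_ids)

  for (p in config$planted) {
    len <- circ_len[[p$circ_id]]
    n_per_mir <- pmax(1L, as.integer(round(p$sites_per_kb * len / 1000)))
    total <- n_per_mir * length(p$mir_ids)
    slots <- seq(1L, len - 7L, by = 8L)
    if (total > length(slots))
      stop("generate_fixtures: planted site density (", p$sites_per_kb,
           "/kb) implies ", total, " sites but sequence '", p$circ_id,
           "' has room for ", length(slots))
    starts <- sample(slots, total)
    s <- circ_seq_v[[p$circ_id]]
    i <- 0L
    for (m in p$mir_ids) {
      site <- planted_site_seq(mir_seq_v[[m]])
      for (r in seq_len(n_per_mir)) {
        i <- i + 1L
        substr(s, starts[i], starts[i] + 7L) <- site
      }
    }
    circ_seq_v[[p$circ_id]] <- s
  }

  # gene sets: a disjoint partition of the universe
  split_sizes <- rep(config$n_gene %/% config$n_sets, config$n_sets)
  split_sizes[seq_len(config$n_gene %% config$n_sets)] <-
    split_sizes[seq_len(config$n_gene %% config$n_sets)] + 1L
  idx_end <- cumsum(split_sizes)
  idx_start <- c(1L, utils::head(idx_end, -1L) + 1L)
  sets <- setNames(lapply(seq_len(config$n_sets), function(i)
    gene_ids[idx_start[i]:idx_end[i]]), set_names)

  # miRNA-gene evidence: sparse background, boosted planted-mir -> target
  # set pairs in both sources
  bg_mask <- matrix(stats::runif(config$n_mir * config$n_gene) < 0.08,
                    config$n_mir, config$n_gene,
                    dimnames = list(mir_ids, gene_ids))
  bg_pairs <- which(bg_mask, arr.ind = TRUE)
  ts <- data.frame(mir_id = mir_ids[bg_pairs[, 1L]],
                   gene_id = gene_ids[bg_pairs[, 2L]],
                   n_mre = 1L + stats::rpois(nrow(bg_pairs), 0.7),
                   stringsAsFactors = FALSE)
  keep_mtb <- stats::runif(nrow(bg_pairs)) < 0.5
  mtb <- data.frame(mir_id = ts$mir_id[keep_mtb],
                    gene_id = ts$gene_id[keep_mtb],
                    n_pubs = 1L + stats::rpois(sum(keep_mtb), 0.5),
                    stringsAsFactors = FALSE)
  for (p in config$planted) {
    tg <- sets[[p$target_set]]
    grid <- expand.grid(mir_id = p$mir_ids, gene_id = tg,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    ts <- rbind(ts, data.frame(grid, n_mre = 4L + stats::rpois(nrow(grid), 2)))
    mtb <- rbind(mtb, data.frame(grid, n_pubs = 3L + stats::rpois(nrow(grid), 2)))
  }

  structure(list(
    circ_expr = expression_panel(circ_v, "circRNA", "SRPBM"),
    mir_expr = expression_panel(mir_v, "miRNA", "CPM"),
    circ_seqs = sequence_set(circ_seq_v),
    mir_seqs = sequence_set(mir_seq_v),
    targetscan = ts, mirtarbase = mtb,
    gene_sets = gene_set_collection(sets),
    reference = planted_circ,
    config = config), class = "fixture_bundle")
}

#' Write a fixture bundle to disk in the pipeline's input formats
#'
#' Expression panels as TSV, sequences as FASTA, evidence tables as TSV,
#' gene sets as GMT and the reference circRNA list as one id per line --
#' the same formats the package's readers consume.
#'
#' @param bundle A `fixture_bundle` from [generate_fixtures()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of the files written, invisibly.
#' @export
write_fixtures <- function(bundle, dir) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    circ_expr = file.path(dir, "circ_expression.tsv"),
    mir_expr = file.path(dir, "mir_expression.tsv"),
    circ_seqs = file.path(dir, "circ_sequences.fasta"),
    mir_seqs = file.path(dir, "mir_sequences.fasta"),
    targetscan = file.path(dir, "targetscan_evidence.tsv"),
    mirtarbase = file.path(dir, "mirtarbase_evidence.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    reference = file.path(dir, "reference_circrnas.txt"))
  write_expression_tsv(bundle$circ_expr, paths[["circ_expr"]])
  write_expression_tsv(bundle$mir_expr, paths[["mir_expr"]])
  write_fasta(bundle$circ_seqs, paths[["circ_seqs"]])
  write_fasta(bundle$mir_seqs, paths[["mir_seqs"]])
  utils::write.table(bundle$targetscan, paths[["targetscan"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$mirtarbase, paths[["mirtarbase"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(bundle$gene_sets, paths[["gene_sets"]])
  writeLines(bundle$reference, paths[["reference"]])
  invisible(paths)
}
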
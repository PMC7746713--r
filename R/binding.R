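# Canonical miRNA seed-site counting on circRNA mature sequences, the
# length-normalized circRNA-miRNA binding score, and assembly of
# miRNA-gene evidence tables.
#
# Site taxonomy is the canonical seed-site hierarchy: the seed is miRNA
# positions 2-7 (5'->3'); a target site carries the reverse complement of
# the seed, optionally extended by a match to miRNA position 8 on its 5'
# side (m8) and/or an adenosine opposite miRNA position 1 on its 3' side
# (A1 anchor). This is a site COUNTER: no context/conservation scoring is
# attempted, because only the number of sites per target enters the
# binding score.

SITE_TYPES <- c("6mer", "7mer-A1", "7mer-m8", "8mer")
SITE_LENGTHS <- c(`6mer` = 6L, `7mer-A1` = 7L, `7mer-m8` = 7L, `8mer` = 8L)

rna_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

#' Find canonical miRNA seed-match sites on a target sequence
#'
#' Scans the target (5'->3') for reverse-complement matches to the miRNA
#' seed (positions 2-7 of the mature miRNA). Each seed match is classified
#' by two independent features: a match to miRNA position 8 immediately 5'
#' of the seed match on the target (m8), and an `A` immediately 3' of it,
#' opposite miRNA position 1 (A1 anchor). Both present gives an 8mer, m8
#' alone a 7mer-m8, the anchor alone a 7mer-A1, neither a 6mer. Overlapping
#' seed matches at different offsets are all reported.
#'
#' With `circular = TRUE` the target is treated as a circle: seed matches
#' may span the back-splice junction and the m8/A1 flanks wrap around the
#' sequence end. Start positions are reported modulo the target length.
#'
#' @param mirna Mature miRNA sequence (character scalar, RNA alphabet,
#'   >= 8 nt) or a single-element [sequence_set()].
#' @param target Target sequence (character scalar or single-element
#'   [sequence_set()]); targets shorter than 6 nt yield no hits.
#' @param circular Scan the target as a circle (default `FALSE`).
#' @return A data.frame with columns `position` (0-based start of the full
#'   site on the target, half-open), `core_position` (0-based start of the
#'   6-nt seed match itself), `length` (site length in nt) and `site_type`,
#'   ordered by position. Zero rows when there is no hit.
#' @export
find_seed_sites <- function(mirna, target, circular = FALSE) {
  mirna <- chartr("T", "U", toupper(as.character(mirna)[1L]))
  target <- chartr("T", "U", toupper(as.character(target)[1L]))
  if (nchar(mirna) < 8L)
    stop("find_seed_sites: miRNA must be >= 8 nt")
  L <- nchar(target)
  empty <- data.frame(position = integer(0), core_position = integer(0),
                      length = integer(0), site_type = character(0),
                      stringsAsFactors = FALSE)
  if (L < 6L) return(empty)
  seed_rc <- rna_revcomp(substr(mirna, 2L, 7L))          # pairs m7..m2
  m8_rc <- chartr("ACGU", "UGCA", substr(mirna, 8L, 8L)) # pairs m8
  tb <- strsplit(target, "", fixed = TRUE)[[1L]]
  sb <- strsplit(seed_rc, "", fixed = TRUE)[[1L]]
  if (circular) {
    ext <- c(tb, tb[seq_len(min(7L, L))])
    starts <- seq_len(L)                    # all rotations once
  } else {
    ext <- tb
    starts <- seq_len(L - 5L)
  }
  ok <- rep(TRUE, length(starts))
  for (j in 0:5) ok <- ok & ext[starts + j] == sb[j + 1L]
  cores <- starts[ok]                        # 1-based seed-match starts
  if (!length(cores)) return(empty)
  # flanks: 5' base pairs m8, 3' base pairs m1 (A anchor)
  if (circular) {
    five <- tb[((cores - 2L) %% L) + 1L]
    three <- tb[((cores + 5L) %% L) + 1L]
    has_m8 <- five == m8_rc
    has_a1 <- three == "A"
  } else {
    has_m8 <- cores > 1L & tb[pmax(cores - 1L, 1L)] == m8_rc
    has_a1 <- cores + 6L <= L & tb[pmin(cores + 6L, L)] == "A"
  }
  type <- ifelse(has_m8 & has_a1, "8mer",
          ifelse(has_m8, "7mer-m8",
          ifelse(has_a1, "7mer-A1", "6mer")))
  start0 <- cores - 1L - as.integer(has_m8)  # site start includes the m8 base
  if (circular) start0 <- start0 %% L
  res <- data.frame(position = as.integer(start0),
                    core_position = as.integer(cores - 1L),
                    length = unname(SITE_LENGTHS[type]),
                    site_type = type, stringsAsFactors = FALSE)
  res <- unique(res)
  res[order(res$position, res$site_type), , drop = FALSE]
}

#' Count seed sites for every miRNA against every target
#'
#' Convenience wrapper running [find_seed_sites()] over the cross product
#' of a target set and a miRNA set.
#'
#' @param targets [sequence_set()] of target (circRNA mature) sequences.
#' @param mirnas [sequence_set()] of mature miRNA sequences.
#' @param circular Treat targets as circles (default `TRUE`: circRNA mature
#'   sequences are covalently closed).
#' @param min_site_type Weakest site type to count, one of
#'   `"6mer"`, `"7mer-A1"`, `"7mer-m8"`, `"8mer"` (hierarchy in that
#'   order); default counts all canonical sites.
#' @return Integer matrix of site counts, targets x miRNAs.
#' @export
count_seed_sites <- function(targets, mirnas, circular = TRUE,
                             min_site_type = "6mer") {
  min_rank <- match(match.arg(min_site_type, SITE_TYPES), SITE_TYPES)
  keep_types <- SITE_TYPES[seq(min_rank, length(SITE_TYPES))]
  n <- matrix(0L, length(targets), length(mirnas),
              dimnames = list(names(targets), names(mirnas)))
  for (mi in seq_along(mirnas)) {
    for (ti in seq_along(targets)) {
      hits <- find_seed_sites(mirnas[[mi]], targets[[ti]], circular = circular)
      n[ti, mi] <- sum(hits$site_type %in% keep_types)
    }
  }
  n
}

#' Length-normalized circRNA-miRNA binding scores
#'
#' The raw evidence is the number of miRNA response elements (MREs) on the
#' circRNA mature sequence; because longer sequences accumulate more sites
#' by chance, the count is normalized by mature-sequence length and
#' expressed in MREs per kilobase: `mre_per_kb = n_mre * 1000 / length_nt`.
#'
#' @param site_counts Integer matrix of MRE counts (targets x miRNAs), as
#'   from [count_seed_sites()], or a data.frame with columns
#'   `circ_id`, `mir_id`, `n_mre`.
#' @param mature_lengths Named integer vector of mature-sequence lengths in
#'   nt, covering every target id.
#' @return A data.frame of class `binding_score_table` with columns
#'   `circ_id`, `mir_id`, `n_mre`, `mature_length_nt`, `mre_per_kb`.
#' @export
binding_score <- function(site_counts, mature_lengths) {
  if (is.matrix(site_counts)) {
    df <- data.frame(
      circ_id = rep(rownames(site_counts), times = ncol(site_counts)),
      mir_id = rep(colnames(site_counts), each = nrow(site_counts)),
      n_mre = as.integer(site_counts),
      stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("circ_id", "mir_id", "n_mre") %in% names(site_counts)))
    df <- site_counts[, c("circ_id", "mir_id", "n_mre")]
  }
  if (any(df$n_mre < 0)) stop("binding_score: negative MRE count")
  missing <- setdiff(unique(df$circ_id), names(mature_lengths))
  if (length(missing))
    stop("binding_score: no mature length for: ",
         paste(utils::head(missing, 3), collapse = ", "))
  len <- unname(mature_lengths[df$circ_id])
  if (any(len <= 0)) stop("binding_score: mature length must be > 0")
  df$mature_length_nt <- as.integer(len)
  df$mre_per_kb <- df$n_mre * 1000 / len
  rownames(df) <- NULL
  class(df) <- c("binding_score_table", "data.frame")
  df
}

#' Load and merge miRNA-gene evidence tables
#'
#' Combines a TargetScan-style table of predicted MRE counts per
#' (miRNA, gene) pair with a miRTarBase-style table of supporting
#' publication counts. Pairs are outer-joined; evidence absent from one
#' source is filled with 0, and duplicate rows for a pair (e.g. conserved
#' and nonconserved site families) are summed.
#'
#' @param targetscan Path to a TSV with columns `mir_id`, `gene_id`,
#'   `n_mre`, or a data.frame with those columns, or `NULL`.
#' @param mirtarbase Path to a TSV with columns `mir_id`, `gene_id`,
#'   `n_pubs`, or a data.frame with those columns, or `NULL`.
#' @param id_map Optional data.frame (`from`, `to`) mapping miRNA family
#'   names to mature miRNA ids before merging; unmapped ids pass through.
#' @return A data.frame of class `mir_gene_evidence` with columns `mir_id`,
#'   `gene_id`, `n_mre_targetscan`, `n_pubs_mirtarbase`; every row has at
#'   least one positive evidence count.
#' @export
load_mir_gene_evidence <- function(targetscan = NULL, mirtarbase = NULL,
                                   id_map = NULL) {
  read_ev <- function(x, count_col) {
    if (is.null(x)) return(NULL)
    if (is.character(x))
      x <- utils::read.table(x, sep = "\t", header = TRUE, comment.char = "#",
                             stringsAsFactors = FALSE)
    need <- c("mir_id", "gene_id", count_col)
    if (!all(need %in% names(x)))
      stop("load_mir_gene_evidence: table must have columns ",
           paste(need, collapse = ", "))
    if (any(x[[count_col]] < 0))
      stop("load_mir_gene_evidence: negative count in '", count_col, "'")
    if (!is.null(id_map)) {
      hit <- match(x$mir_id, id_map$from)
      x$mir_id[!is.na(hit)] <- id_map$to[hit[!is.na(hit)]]
    }
    agg <- stats::aggregate(x[[count_col]],
                            by = list(mir_id = x$mir_id, gene_id = x$gene_id),
                            FUN = sum)
    names(agg)[3L] <- count_col
    agg
  }
  ts <- read_ev(targetscan, "n_mre")
  mtb <- read_ev(mirtarbase, "n_pubs")
  if (is.null(ts) && is.null(mtb))
    stop("load_mir_gene_evidence: at least one evidence table is required")
  if (is.null(ts))
    out <- data.frame(mtb[1:2], n_mre_targetscan = 0, n_pubs_mirtarbase = mtb$n_pubs)
  else if (is.null(mtb))
    out <- data.frame(ts[1:2], n_mre_targetscan = ts$n_mre, n_pubs_mirtarbase = 0)
  else {
    out <- merge(ts, mtb, by = c("mir_id", "gene_id"), all = TRUE)
    out$n_mre[is.na(out$n_mre)] <- 0
    out$n_pubs[is.na(out$n_pubs)] <- 0
    names(out)[match(c("n_mre", "n_pubs"), names(out))] <-
      c("n_mre_targetscan", "n_pubs_mirtarbase")
  }
  out <- out[out$n_mre_targetscan > 0 | out$n_pubs_mirtarbase > 0, , drop = FALSE]
  out <- out[order(out$mir_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mir_gene_evidence", "data.frame")
  out
}
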
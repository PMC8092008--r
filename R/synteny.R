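# Construction of triple-conserved-synteny pillars: homology filtering,
# tandem collapsing, the synteny objective, simulated-annealing layout
# search per polyploid genome, and cross-genome merging with a global
# pillar order.
#
# Gene positions are order indices along a chromosome (synteny is an
# order property here), and two genes are "adjacent" when their indices
# differ by at most the window w (default 1 = strict neighbours).

#' Filter homology pairs on identity and length ratio
#'
#' Keeps pairs whose percent amino-acid identity and shorter/longer
#' length ratio meet the thresholds; both boundaries are inclusive.
#'
#' @param pairs data.frame with columns `identity` and `length_ratio`
#'   (both in `[0, 1]`), plus any id columns.
#' @param min_identity,min_length_ratio thresholds (defaults 0.70, 0.80).
#' @return the retained rows of `pairs`.
#' @examples
#' filter_homologs(data.frame(identity = c(.7, .69), length_ratio = c(.8, .95)))
#' @export
filter_homologs <- function(pairs, min_identity = 0.70,
                            min_length_ratio = 0.80) {
  stopifnot(all(c("identity", "length_ratio") %in% names(pairs)))
  bad <- pairs$identity < 0 | pairs$identity > 1 |
    pairs$length_ratio < 0 | pairs$length_ratio > 1
  if (any(bad, na.rm = TRUE) || anyNA(bad)) {
    stop("identity and length_ratio must lie in [0, 1]")
  }
  pairs[pairs$identity >= min_identity &
          pairs$length_ratio >= min_length_ratio, , drop = FALSE]
}

#' Collapse runs of tandem-duplicated outgroup genes into anchors
#'
#' Outgroup genes that are homologous to each other and lie within
#' `max_gap` positions on the same chromosome are merged (by transitive
#' closure) into a single anchor, which then heads one pillar.
#'
#' @param outgroup data.frame with columns `chrom`, `pos`, `gene`.
#' @param intra_pairs data.frame of intra-outgroup homolog pairs, columns
#'   `gene1`, `gene2` (may be empty).
#' @param max_gap maximum position gap for tandem merging (default 1).
#' @return data.frame `gene`, `anchor` (anchor = lowest-position member
#'   of the tandem group), ordered by position.
#' @export
collapse_tandems <- function(outgroup, intra_pairs = NULL, max_gap = 1) {
  stopifnot(all(c("chrom", "pos", "gene") %in% names(outgroup)))
  outgroup <- outgroup[order(outgroup$chrom, outgroup$pos), , drop = FALSE]
  n <- nrow(outgroup)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (!is.null(intra_pairs) && nrow(intra_pairs)) {
    idx <- stats::setNames(seq_len(n), outgroup$gene)
    for (r in seq_len(nrow(intra_pairs))) {
      i <- idx[[as.character(intra_pairs$gene1[r])]]
      j <- idx[[as.character(intra_pairs$gene2[r])]]
      if (is.null(i) || is.null(j)) next
      if (outgroup$chrom[i] == outgroup$chrom[j] &&
          abs(outgroup$pos[i] - outgroup$pos[j]) <= max_gap) {
        ri <- find(i); rj <- find(j)
        parent[max(ri, rj)] <- min(ri, rj)
      }
    }
    # transitive closure through adjacency: repeat until stable
    repeat {
      changed <- FALSE
      for (r in seq_len(nrow(intra_pairs))) {
        i <- idx[[as.character(intra_pairs$gene1[r])]]
        j <- idx[[as.character(intra_pairs$gene2[r])]]
        if (is.null(i) || is.null(j)) next
        if (outgroup$chrom[i] != outgroup$chrom[j]) next
        if (abs(outgroup$pos[i] - outgroup$pos[j]) > max_gap) next
        ri <- find(i); rj <- find(j)
        if (ri != rj) { parent[max(ri, rj)] <- min(ri, rj); changed <- TRUE }
      }
      if (!changed) break
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  data.frame(gene = outgroup$gene, anchor = outgroup$gene[roots],
             stringsAsFactors = FALSE)
}

#' A per-genome pillar layout
#'
#' @param anchors character vector of anchor ids in pillar order.
#' @param assign character matrix (pillars x 3 tracks) of polyploid gene
#'   ids, `NA` for empty slots; rows follow `anchors`.
#' @param genome genome label.
#' @return an object of class `"pillar_layout"`.
#' @export
pillar_layout <- function(anchors, assign, genome = "genome") {
  assign <- as.matrix(assign)
  stopifnot(nrow(assign) == length(anchors), ncol(assign) == 3L)
  genes <- assign[!is.na(assign)]
  if (anyDuplicated(genes)) stop("every gene may be assigned only once")
  rownames(assign) <- anchors
  structure(list(anchors = as.character(anchors), assign = assign,
                 genome = genome),
            class = "pillar_layout")
}

#' Triple-conserved-synteny score of a layout
#'
#' The score counts, over adjacent pillar pairs and tracks, the gene
#' pairs that are syntenic neighbours (same chromosome, order indices
#' within `w`); `tcs_breaks()` counts the occupied adjacent track pairs
#' that violate it.
#'
#' @param layout a [pillar_layout()].
#' @param genes data.frame with columns `chrom`, `pos`, `gene` for the
#'   layout's genome.
#' @param w adjacency window (default 1 = strict neighbours).
#' @return integer score (or break count).
#' @export
tcs_objective <- function(layout, genes, w = 1) {
  tcs_counts(layout, genes, w)["score"]
}

#' @rdname tcs_objective
#' @export
tcs_breaks <- function(layout, genes, w = 1) {
  tcs_counts(layout, genes, w)["breaks"]
}

tcs_counts <- function(layout, genes, w = 1) {
  a <- layout$assign
  n <- nrow(a)
  if (n < 2L) return(c(score = 0L, breaks = 0L))
  chrom <- stats::setNames(as.character(genes$chrom), genes$gene)
  pos <- stats::setNames(genes$pos, genes$gene)
  score <- 0L
  breaks <- 0L
  for (i in seq_len(n - 1L)) {
    for (tr in 1:3) {
      g1 <- a[i, tr]; g2 <- a[i + 1L, tr]
      if (is.na(g1) || is.na(g2)) next
      if (chrom[[g1]] == chrom[[g2]] && abs(pos[[g1]] - pos[[g2]]) <= w) {
        score <- score + 1L
      } else {
        breaks <- breaks + 1L
      }
    }
  }
  c(score = score, breaks = breaks)
}

#' One random ordering move: relocate or reverse a small block
#'
#' Relocation handles transpositions; reversal handles inversions, which
#' relocation alone cannot undo.
#' @noRd
propose_order_move <- function(ord) {
  n <- length(ord)
  len <- sample.int(min(3L, n - 1L), 1L) + sample.int(2L, 1L) - 1L
  len <- min(len, n - 1L)
  from <- sample.int(n - len + 1L, 1L)
  block <- from:(from + len - 1L)
  if (stats::runif(1) < 0.5) {
    ord[block] <- rev(ord[block])            # reverse in place
    ord
  } else {
    rest <- ord[-block]
    at <- sample.int(length(rest) + 1L, 1L) - 1L
    append(rest, ord[block], after = at)
  }
}

#' Greedy initial layout from filtered homology pairs
#'
#' Assigns each polyploid gene to the free track slot of its
#' highest-identity candidate anchor (anchors ordered by outgroup
#' position); genes whose candidate pillars are all full are left out
#' with a message.
#'
#' @param anchors character vector of anchors in outgroup order.
#' @param homologs filtered pairs with columns `anchor`, `gene`,
#'   `identity`.
#' @param genome genome label.
#' @return a [pillar_layout()].
#' @export
initial_layout <- function(anchors, homologs, genome = "genome") {
  stopifnot(all(c("anchor", "gene", "identity") %in% names(homologs)))
  assign <- matrix(NA_character_, length(anchors), 3L)
  rownames(assign) <- anchors
  h <- homologs[order(-homologs$identity), , drop = FALSE]
  h <- h[!duplicated(paste(h$anchor, h$gene)), , drop = FALSE]
  dropped <- 0L
  for (gene in unique(h$gene)) {
    cand <- h$anchor[h$gene == gene]
    placed <- FALSE
    for (anc in cand) {
      if (!anc %in% anchors) next
      free <- which(is.na(assign[anc, ]))
      if (length(free)) {
        assign[anc, free[1]] <- gene
        placed <- TRUE
        break
      }
    }
    if (!placed) dropped <- dropped + 1L
  }
  if (dropped) message(dropped, " gene(s) not placed (candidate pillars full)")
  pillar_layout(anchors, assign, genome)
}

#' Optimize a pillar layout by simulated annealing
#'
#' Maximizes [tcs_objective()] with Metropolis moves: move a gene to a
#' free slot of another pillar whose anchor it is homologous to, swap
#' two track slots within a pillar, or relocate a block of consecutive
#' pillars.  Geometric cooling; the best layout ever seen is returned,
#' so the result never scores below the input.
#'
#' @param layout a [pillar_layout()].
#' @param genes gene-order table for the genome (`chrom`, `pos`, `gene`).
#' @param homologs optional pairs (`anchor`, `gene`) defining legal gene
#'   moves; `NULL` disables the gene-move proposal.
#' @param w adjacency window.
#' @param schedule list overriding `T0 = 1`, `cooling = 0.995`,
#'   `patience = 200` (sweeps without improvement before stopping),
#'   `max_sweeps = 2000`, `moves_per_sweep` (default `10 * n pillars`).
#' @param seed integer seed (same seed, same result).
#' @return the best [pillar_layout()] found, with attribute `"score"`.
#' @export
anneal_layout <- function(layout, genes, homologs = NULL, w = 1,
                          schedule = list(), seed = 1) {
  stopifnot(inherits(layout, "pillar_layout"))
  sch <- utils::modifyList(
    list(T0 = 1, cooling = 0.995, patience = 200, max_sweeps = 2000,
         moves_per_sweep = max(10L * length(layout$anchors), 20L)),
    schedule)
  set.seed(seed)

  cand <- NULL
  if (!is.null(homologs)) {
    cand <- split(as.character(homologs$anchor), as.character(homologs$gene))
  }

  cur <- layout
  cur_score <- unname(tcs_objective(cur, genes, w))
  best <- cur
  best_score <- cur_score
  n <- length(cur$anchors)
  temp <- sch$T0
  stale <- 0L

  propose <- function(lay) {
    move <- sample.int(3L, 1L)
    a <- lay$assign
    if (move == 1L && !is.null(cand)) {
      genes_in <- which(!is.na(a), arr.ind = TRUE)
      if (!nrow(genes_in)) return(lay)
      pick <- genes_in[sample.int(nrow(genes_in), 1L), ]
      gene <- a[pick[1], pick[2]]
      anchors_ok <- intersect(cand[[gene]], lay$anchors)
      anchors_ok <- setdiff(anchors_ok, lay$anchors[pick[1]])
      if (!length(anchors_ok)) return(lay)
      tgt <- sample(anchors_ok, 1L)
      free <- which(is.na(a[tgt, ]))
      if (!length(free)) return(lay)
      a[tgt, free[1]] <- gene
      a[pick[1], pick[2]] <- NA
      lay$assign <- a
    } else if (move == 2L) {
      i <- sample.int(n, 1L)
      tr <- sample.int(3L, 2L)
      a[i, tr] <- a[i, rev(tr)]
      lay$assign <- a
    } else {
      if (n < 2L) return(lay)
      ord <- propose_order_move(seq_len(n))
      lay$anchors <- lay$anchors[ord]
      lay$assign <- lay$assign[ord, , drop = FALSE]
    }
    lay
  }

  for (sweep in seq_len(sch$max_sweeps)) {
    improved <- FALSE
    for (m in seq_len(sch$moves_per_sweep)) {
      prop <- propose(cur)
      new_score <- unname(tcs_objective(prop, genes, w))
      d <- new_score - cur_score
      if (d >= 0 || stats::runif(1) < exp(d / temp)) {
        cur <- prop
        cur_score <- new_score
        if (cur_score > best_score) {
          best <- cur
          best_score <- cur_score
          improved <- TRUE
        }
      }
    }
    temp <- temp * sch$cooling
    stale <- if (improved) 0L else stale + 1L
    if (stale >= sch$patience) break
  }
  attr(best, "score") <- best_score
  best
}

#' Merge per-genome layouts and order the joint pillars
#'
#' Joins per-genome pillar layouts on their shared outgroup anchors,
#' keeps only pillars with at least one surviving gene in every genome,
#' and anneals a global pillar order that minimizes the total number of
#' synteny breaks across the genomes.  Per-genome break flags in the
#' returned pillar set mark pillars with no syntenic support from their
#' predecessor in that genome.
#'
#' @param layouts named list of [pillar_layout()]s (names = genomes).
#' @param genes gene-order table covering all genomes (`genome`,
#'   `chrom`, `pos`, `gene`).
#' @param w adjacency window.
#' @param schedule,seed as in [anneal_layout()].
#' @return a [pillar_set()] ordered by the annealed global order.
#' @export
merge_and_order <- function(layouts, genes, w = 1, schedule = list(),
                            seed = 1) {
  stopifnot(is.list(layouts), length(layouts) >= 1L,
            !is.null(names(layouts)))
  genomes <- names(layouts)
  anchors <- unique(unlist(lapply(layouts, `[[`, "anchors")))

  occupied <- sapply(layouts, function(l) {
    anchors %in% l$anchors[rowSums(!is.na(l$assign)) > 0]
  })
  if (is.null(dim(occupied))) occupied <- matrix(occupied, nrow = 1)
  keep <- rowSums(occupied) == length(genomes)
  anchors <- anchors[keep]
  if (!length(anchors)) stop("no pillar is occupied in every genome")

  gmat <- lapply(layouts, function(l) {
    m <- matrix(NA_character_, length(anchors), 3L)
    hit <- match(anchors, l$anchors)
    ok <- !is.na(hit)
    m[ok, ] <- l$assign[hit[ok], , drop = FALSE]
    m
  })

  per_genome_counts <- function(ord) {
    tot <- 0L
    for (g in seq_along(genomes)) {
      lay <- pillar_layout(anchors[ord], gmat[[g]][ord, , drop = FALSE],
                           genomes[g])
      tot <- tot + unname(tcs_breaks(lay, genes[genes$genome == genomes[g], ],
                                     w))
    }
    tot
  }

  # anneal the order only (block-relocation moves)
  set.seed(seed)
  sch <- utils::modifyList(
    list(T0 = 1, cooling = 0.995, patience = 200, max_sweeps = 1000,
         moves_per_sweep = max(10L * length(anchors), 20L)),
    schedule)
  n <- length(anchors)
  cur <- best <- seq_len(n)
  cur_b <- best_b <- per_genome_counts(cur)
  temp <- sch$T0
  stale <- 0L
  if (n >= 2L) {
    for (sweep in seq_len(sch$max_sweeps)) {
      improved <- FALSE
      for (m in seq_len(sch$moves_per_sweep)) {
        prop <- propose_order_move(cur)
        pb <- per_genome_counts(prop)
        d <- cur_b - pb
        if (d >= 0 || stats::runif(1) < exp(d / temp)) {
          cur <- prop
          cur_b <- pb
          if (cur_b < best_b) { best <- cur; best_b <- cur_b; improved <- TRUE }
        }
      }
      temp <- temp * sch$cooling
      stale <- if (improved) 0L else stale + 1L
      if (stale >= sch$patience) break
    }
  }

  ord <- best
  pattern <- matrix(0L, n, length(genomes))
  breaks <- matrix(FALSE, n, length(genomes))
  genes_out <- vector("list", length(genomes))
  for (g in seq_along(genomes)) {
    a <- gmat[[g]][ord, , drop = FALSE]
    pattern[, g] <- (!is.na(a)) %*% c(1L, 2L, 4L)
    genes_out[[g]] <- a
    gg <- genes[genes$genome == genomes[g], ]
    chrom <- stats::setNames(as.character(gg$chrom), gg$gene)
    pos <- stats::setNames(gg$pos, gg$gene)
    if (n >= 2L) {
      for (i in 2:n) {
        support <- FALSE
        for (tr in 1:3) {
          g1 <- a[i - 1L, tr]; g2 <- a[i, tr]
          if (is.na(g1) || is.na(g2)) next
          if (chrom[[g1]] == chrom[[g2]] && abs(pos[[g1]] - pos[[g2]]) <= w) {
            support <- TRUE
            break
          }
        }
        breaks[i, g] <- !support
      }
    }
  }
  ps <- pillar_set(pattern, genomes = genomes, breaks = breaks,
                   ids = paste0("pillar", seq_len(n)),
                   anchors = anchors[ord], genes = genes_out)
  attr(ps, "total_breaks") <- best_b
  ps
}
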
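# Ancestral gene-order reconstruction: homology sets (with per-genome
# caps), adjacency collection over extant genomes, exact maximum-weight
# matching on the set-endpoint graph, contig filtering, and a second
# matching iteration that orders the contigs.
#
# Each homology set contributes two endpoint nodes (head and tail); a
# candidate adjacency joins one endpoint of each of two sets, weighted
# by the number of genome gene-copy adjacencies supporting it.  A
# matching uses each endpoint at most once, so selected adjacencies plus
# the internal head-tail links chain the sets into simple paths.

#' Build homology sets from a filtered homology graph
#'
#' Fallback constructor: sets are connected components of the homology
#' graph, split greedily (largest components first) whenever a component
#' exceeds the per-genome membership caps.
#'
#' @param pairs data.frame of homologous gene pairs, columns `gene1`,
#'   `gene2`.
#' @param gene_genomes data.frame with columns `gene`, `genome`.
#' @param caps named integer vector: maximum members per genome (e.g.
#'   `c(outgroup = 1, polyploid = 3)`).
#' @return data.frame `set_id`, `genome`, `gene`.
#' @export
build_homology_sets <- function(pairs, gene_genomes, caps) {
  stopifnot(all(c("gene1", "gene2") %in% names(pairs)),
            all(c("gene", "genome") %in% names(gene_genomes)),
            !is.null(names(caps)))
  genome_of <- stats::setNames(as.character(gene_genomes$genome),
                               gene_genomes$gene)
  g <- igraph::graph_from_data_frame(
    pairs[, c("gene1", "gene2")], directed = FALSE,
    vertices = unique(gene_genomes$gene))
  comp <- igraph::components(g)$membership
  out <- list()
  sid <- 0L
  for (cid in order(-table(comp))) {
    genes <- names(comp)[comp == as.integer(names(table(comp))[cid])]
    repeat {
      sid <- sid + 1L
      taken <- character(0)
      used <- stats::setNames(integer(length(caps)), names(caps))
      for (gene in genes) {
        gen <- genome_of[[gene]]
        cap <- caps[[gen]]
        if (is.null(cap)) cap <- 1L
        if (used[[gen]] < cap) {
          taken <- c(taken, gene)
          used[[gen]] <- used[[gen]] + 1L
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        set_id = paste0("set", sid), genome = unname(genome_of[taken]),
        gene = taken, stringsAsFactors = FALSE)
      genes <- setdiff(genes, taken)
      if (!length(genes)) break
    }
  }
  do.call(rbind, out)
}

#' Collect weighted adjacency candidates between homology sets
#'
#' Walks every chromosome of every genome in gene order; each pair of
#' consecutive genes that belong to two different homology sets records
#' one support for the adjacency between those sets.  The traversal
#' orients each occurrence, so the candidate joins the tail endpoint of
#' the first set to the head endpoint of the second (endpoints stored in
#' canonical order).
#'
#' @param genes data.frame `genome`, `chrom`, `pos`, `gene`.
#' @param sets data.frame `set_id`, `genome`, `gene`; a gene may belong
#'   to at most one set.
#' @return data.frame `set_a`, `end_a`, `set_b`, `end_b`, `weight`.
#' @export
collect_adjacencies <- function(genes, sets) {
  stopifnot(all(c("genome", "chrom", "pos", "gene") %in% names(genes)),
            all(c("set_id", "gene") %in% names(sets)))
  if (anyDuplicated(sets$gene)) {
    stop("a gene may belong to at most one homology set")
  }
  set_of <- stats::setNames(as.character(sets$set_id), sets$gene)
  reg <- new.env(parent = emptyenv())
  for (gm in unique(genes$genome)) {
    gg <- genes[genes$genome == gm, , drop = FALSE]
    for (ch in unique(gg$chrom)) {
      cc <- gg[gg$chrom == ch, , drop = FALSE]
      cc <- cc[order(cc$pos), , drop = FALSE]
      # adjacency is defined on the gene order restricted to set members
      cc <- cc[cc$gene %in% names(set_of), , drop = FALSE]
      if (nrow(cc) < 2L) next
      for (i in seq_len(nrow(cc) - 1L)) {
        sa <- set_of[[cc$gene[i]]]
        sb <- set_of[[cc$gene[i + 1L]]]
        if (sa == sb) next
        ends <- c("tail", "head")
        if (sb < sa) { tmp <- sa; sa <- sb; sb <- tmp; ends <- rev(ends) }
        key <- paste(sa, ends[1], sb, ends[2], sep = "\r")
        reg[[key]] <- (reg[[key]] %||% 0L) + 1L
      }
    }
  }
  keys <- ls(reg)
  if (!length(keys)) {
    return(data.frame(set_a = character(0), end_a = character(0),
                      set_b = character(0), end_b = character(0),
                      weight = integer(0), stringsAsFactors = FALSE))
  }
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  data.frame(set_a = parts[, 1], end_a = parts[, 2],
             set_b = parts[, 3], end_b = parts[, 4],
             weight = vapply(keys, function(k) reg[[k]], integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Exact maximum-weight matching on an endpoint graph
#'
#' Branch-and-bound per connected component with a suffix-weight upper
#' bound; exact on the component sizes that arise in gene-adjacency
#' graphs (components are short chains with local conflicts).
#'
#' @param cands candidate data.frame as from [collect_adjacencies()].
#' @return integer vector of selected row indices of `cands`.
#' @noRd
max_weight_matching <- function(cands) {
  m <- nrow(cands)
  if (!m) return(integer(0))
  epa <- paste(cands$set_a, cands$end_a)
  epb <- paste(cands$set_b, cands$end_b)
  eps <- unique(c(epa, epb))
  ia <- match(epa, eps)
  ib <- match(epb, eps)

  g <- igraph::make_graph(rbind(ia, ib), n = length(eps), directed = FALSE)
  comp <- igraph::components(g)$membership
  selected <- integer(0)
  for (cid in unique(comp[ia])) {
    rows <- which(comp[ia] == cid)
    ord <- rows[order(-cands$weight[rows])]
    wts <- cands$weight[ord]
    suffix <- rev(cumsum(rev(wts)))
    best_val <- -1
    best_sel <- integer(0)
    used0 <- character(0)
    rec <- function(i, used, cur, sel) {
      if (cur > best_val) { best_val <<- cur; best_sel <<- sel }
      if (i > length(ord)) return(invisible())
      if (cur + suffix[i] <= best_val) return(invisible())
      a <- epa[ord[i]]; b <- epb[ord[i]]
      if (!(a %in% used) && !(b %in% used)) {
        rec(i + 1L, c(used, a, b), cur + wts[i], c(sel, ord[i]))
      }
      rec(i + 1L, used, cur, sel)
    }
    rec(1L, used0, 0, integer(0))
    selected <- c(selected, best_sel)
  }
  selected
}

#' Chain matched adjacencies into simple paths of sets
#'
#' @param set_ids all set ids.
#' @param sel data.frame of selected candidates.
#' @return list with `paths` (list of list(sets, enter_ends)) and
#'   `broken` (data.frame of cycle-breaking removals).
#' @noRd
chain_matching <- function(set_ids, sel) {
  other_end <- c(head = "tail", tail = "head")
  link <- new.env(parent = emptyenv())   # endpoint -> c(set, end, weight)
  put <- function(s, e, s2, e2, w) {
    key <- paste(s, e)
    if (!is.null(link[[key]])) stop("endpoint used twice in matching")
    link[[key]] <- list(set = s2, end = e2, weight = w)
  }
  if (nrow(sel)) {
    for (r in seq_len(nrow(sel))) {
      put(sel$set_a[r], sel$end_a[r], sel$set_b[r], sel$end_b[r],
          sel$weight[r])
      put(sel$set_b[r], sel$end_b[r], sel$set_a[r], sel$end_a[r],
          sel$weight[r])
    }
  }
  visited <- stats::setNames(rep(FALSE, length(set_ids)), set_ids)
  broken <- list()
  paths <- list()

  walk <- function(start_set, enter_end) {
    sets <- character(0)
    enters <- character(0)
    s <- start_set
    e <- enter_end
    repeat {
      sets <- c(sets, s)
      enters <- c(enters, e)
      visited[[s]] <<- TRUE
      exit <- other_end[[e]]
      nxt <- link[[paste(s, exit)]]
      if (is.null(nxt) || visited[[nxt$set]]) break
      s <- nxt$set
      e <- nxt$end
    }
    list(sets = sets, enter_ends = enters)
  }

  # path starts: sets with a free endpoint
  for (s in set_ids) {
    if (visited[[s]]) next
    free_head <- is.null(link[[paste(s, "head")]])
    free_tail <- is.null(link[[paste(s, "tail")]])
    if (free_head) {
      paths[[length(paths) + 1L]] <- walk(s, "head")
    } else if (free_tail) {
      paths[[length(paths) + 1L]] <- walk(s, "tail")
    }
  }
  # remaining sets sit in cycles: break each at its lowest-weight edge
  for (s in set_ids) {
    if (visited[[s]]) next
    cyc <- walk(s, "head")          # marks members; cycle: find min edge
    min_w <- Inf
    min_at <- 1L
    for (k in seq_along(cyc$sets)) {
      sk <- cyc$sets[k]
      exit <- other_end[[cyc$enter_ends[k]]]
      nxt <- link[[paste(sk, exit)]]
      if (!is.null(nxt) && nxt$weight < min_w) {
        min_w <- nxt$weight
        min_at <- k
      }
    }
    # reopen the cycle just after min_at
    sk <- cyc$sets[min_at]
    exit <- other_end[[cyc$enter_ends[min_at]]]
    nxt <- link[[paste(sk, exit)]]
    rm(list = paste(sk, exit), envir = link)
    rm(list = paste(nxt$set, nxt$end), envir = link)
    broken[[length(broken) + 1L]] <- data.frame(
      set_a = sk, set_b = nxt$set, weight = min_w, stringsAsFactors = FALSE)
    for (m in cyc$sets) visited[[m]] <- FALSE
    start <- nxt$set
    paths[[length(paths) + 1L]] <- walk(start, nxt$end)
  }
  list(paths = paths,
       broken = if (length(broken)) do.call(rbind, broken) else
         data.frame(set_a = character(0), set_b = character(0),
                    weight = numeric(0)))
}

#' Linearize homology sets into ancestral contigs
#'
#' Selects a maximum-weight set of adjacency candidates such that every
#' set endpoint is used at most once, then chains the selected
#' adjacencies into linear contigs.  Cycles in the selection (possible
#' when every endpoint of a loop is matched) are broken at their
#' lowest-weight adjacency, which is recorded.
#'
#' @param cands candidates from [collect_adjacencies()].
#' @param set_ids all set ids (sets without candidates become singleton
#'   contigs).
#' @return list with `contigs` (list of character vectors of set ids in
#'   path order), `total_weight` (selected weight), and `broken_cycles`.
#' @export
mwm_linearize <- function(cands, set_ids = NULL) {
  if (is.null(set_ids)) {
    set_ids <- unique(c(cands$set_a, cands$set_b))
  }
  sel_idx <- max_weight_matching(cands)
  sel <- cands[sel_idx, , drop = FALSE]
  chained <- chain_matching(set_ids, sel)
  total <- sum(sel$weight) - sum(chained$broken$weight)
  list(contigs = lapply(chained$paths, `[[`, "sets"),
       total_weight = total,
       broken_cycles = chained$broken)
}

#' Filter ancestral contigs
#'
#' Drops contigs with too few genes from a required genome ("four or
#' fewer" by default, so five survive) and, when ancestral chromosome
#' labels are available for the sets, contigs whose members are not
#' dominated by a single label.
#'
#' @param contigs list of character vectors of set ids.
#' @param set_genes data.frame `set_id`, `genome`, `gene`.
#' @param required_genome genome whose gene count is checked.
#' @param min_genes contigs with `<= min_genes` genes from
#'   `required_genome` are dropped (default 4).
#' @param chrom_labels optional data.frame `set_id`, `label`.
#' @param majority dominance threshold for the label rule (default 0.8).
#' @return the retained contigs (same list structure).
#' @export
filter_contigs <- function(contigs, set_genes, required_genome,
                           min_genes = 4, chrom_labels = NULL,
                           majority = 0.8) {
  stopifnot(all(c("set_id", "genome") %in% names(set_genes)))
  keep <- vapply(contigs, function(sets) {
    cnt <- sum(set_genes$genome == required_genome &
                 set_genes$set_id %in% sets)
    if (cnt <= min_genes) return(FALSE)
    if (!is.null(chrom_labels)) {
      labs <- chrom_labels$label[chrom_labels$set_id %in% sets]
      if (length(labs)) {
        top <- max(table(labs)) / length(labs)
        if (top < majority) return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  contigs[keep]
}

#' Order contigs by a second round of maximum-weight matching
#'
#' Collects adjacency support between contig ends (consecutive genome
#' genes whose sets terminate two different contigs), matches the contig
#' endpoints exactly as in [mwm_linearize()], and concatenates the
#' contigs along the selected junctions, reversing a contig when it is
#' entered at its tail.
#'
#' @param contigs list of character vectors of set ids (in contig order).
#' @param genes gene-order table (`genome`, `chrom`, `pos`, `gene`).
#' @param sets data.frame `set_id`, `genome`, `gene`.
#' @return list with `chromosomes` (list of character vectors of set ids
#'   spanning the joined contigs) and `junction_weight`.
#' @export
order_contigs <- function(contigs, genes, sets) {
  stopifnot(length(contigs) >= 1L)
  names(contigs) <- paste0("contig", seq_along(contigs))
  set_contig <- stats::setNames(
    rep(names(contigs), lengths(contigs)), unlist(contigs))
  # endpoint of the contig at which each terminal set sits
  terminal_end <- function(ctg, set) {
    sets_in <- contigs[[ctg]]
    if (set == sets_in[1]) "head" else if (set == sets_in[length(sets_in)])
      "tail" else NA_character_
  }

  set_of <- stats::setNames(as.character(sets$set_id), sets$gene)
  reg <- new.env(parent = emptyenv())
  for (gm in unique(genes$genome)) {
    gg <- genes[genes$genome == gm, , drop = FALSE]
    for (ch in unique(gg$chrom)) {
      cc <- gg[gg$chrom == ch, , drop = FALSE]
      cc <- cc[order(cc$pos), , drop = FALSE]
      cc <- cc[cc$gene %in% names(set_of), , drop = FALSE]
      if (nrow(cc) < 2L) next
      for (i in seq_len(nrow(cc) - 1L)) {
        sa <- set_of[[cc$gene[i]]]
        sb <- set_of[[cc$gene[i + 1L]]]
        ca <- set_contig[sa]
        cb <- set_contig[sb]
        if (is.na(ca) || is.na(cb) || ca == cb) next
        ea <- terminal_end(ca, sa)
        eb <- terminal_end(cb, sb)
        if (is.na(ea) || is.na(eb)) next
        ends <- c(ea, eb)
        if (cb < ca) { tmp <- ca; ca <- cb; cb <- tmp; ends <- rev(ends) }
        key <- paste(ca, ends[1], cb, ends[2], sep = "\r")
        reg[[key]] <- (reg[[key]] %||% 0L) + 1L
      }
    }
  }
  keys <- ls(reg)
  cands <- if (length(keys)) {
    parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    data.frame(set_a = parts[, 1], end_a = parts[, 2],
               set_b = parts[, 3], end_b = parts[, 4],
               weight = vapply(keys, function(k) reg[[k]], integer(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(set_a = character(0), end_a = character(0),
               set_b = character(0), end_b = character(0),
               weight = integer(0))
  }

  sel_idx <- max_weight_matching(cands)
  sel <- cands[sel_idx, , drop = FALSE]
  chained <- chain_matching(names(contigs), sel)
  chroms <- lapply(chained$paths, function(p) {
    out <- character(0)
    for (k in seq_along(p$sets)) {
      ctg <- contigs[[p$sets[k]]]
      if (p$enter_ends[k] == "tail") ctg <- rev(ctg)
      out <- c(out, ctg)
    }
    out
  })
  list(chromosomes = chroms,
       junction_weight = sum(sel$weight) - sum(chained$broken$weight))
}
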
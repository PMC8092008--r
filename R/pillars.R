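#' Ordered pillars of triple-conserved synteny
#'
#' A pillar is one post-WGT ancestral locus: per descendant genome it has
#' three track slots (one per parental subgenome, in unknown
#' correspondence) of which at least one holds a surviving gene, plus a
#' flag marking whether syntenic contiguity to the previous pillar is
#' broken in that genome.
#'
#' @param pattern integer matrix `n x G` of presence masks (1..7; bit `s`
#'   set = track slot `s` occupied), or a logical `n x G x 3` array.
#' @param genomes character vector of genome labels (columns of
#'   `pattern`).
#' @param breaks logical `n x G` matrix of synteny-break flags (first row
#'   is ignored by the likelihood); defaults to no breaks.
#' @param ids,anchors optional pillar and outgroup-anchor identifiers.
#' @param genes optional list, one `n x 3` character matrix of gene ids
#'   per genome.
#' @return an object of class `"pillar_set"`.
#' @export
pillar_set <- function(pattern, genomes = colnames(pattern), breaks = NULL,
                       ids = NULL, anchors = NULL, genes = NULL) {
  if (is.array(pattern) && length(dim(pattern)) == 3L) {
    stopifnot(dim(pattern)[3] == 3L)
    pres <- pattern
    pattern <- matrix(0L, dim(pres)[1], dim(pres)[2])
    for (s in 1:3) pattern <- pattern + (pres[, , s] != 0) * c(1L, 2L, 4L)[s]
  }
  pattern <- as.matrix(pattern)
  storage.mode(pattern) <- "integer"
  n <- nrow(pattern)
  G <- ncol(pattern)
  if (is.null(genomes)) genomes <- paste0("genome", seq_len(G))
  if (is.null(breaks)) breaks <- matrix(FALSE, n, G)
  breaks <- as.matrix(breaks)
  storage.mode(breaks) <- "logical"
  if (is.null(ids)) ids <- paste0("pillar", seq_len(n))
  if (is.null(anchors)) anchors <- paste0("anchor", seq_len(n))

  if (n < 1L) stop("a pillar set needs at least one pillar")
  if (any(pattern < 1L | pattern > 7L)) {
    stop("every genome must retain at least one gene in every pillar ",
         "(presence masks must lie in 1..7)")
  }
  if (!all(dim(breaks) == c(n, G))) stop("breaks must be an n x G matrix")
  if (!is.null(genes)) {
    stopifnot(is.list(genes), length(genes) == G)
  }

  structure(
    list(genomes = as.character(genomes), n = n, ids = as.character(ids),
         anchors = as.character(anchors), order_index = seq_len(n),
         pattern = pattern, breaks = breaks, genes = genes),
    class = "pillar_set"
  )
}

#' @method print pillar_set
#' @export
print.pillar_set <- function(x, ...) {
  cat("Pillar set:", x$n, "pillars x", length(x$genomes), "genomes (",
      paste(x$genomes, collapse = ", "), ")\n")
  surv <- colMeans(vapply(seq_along(x$genomes), function(g) {
    rowSums(presence_array(x)[, g, , drop = FALSE])
  }, numeric(x$n)))
  cat("  mean surviving tracks per genome:",
      paste(sprintf("%.2f", surv), collapse = ", "), "\n")
  cat("  synteny breaks flagged:", sum(x$breaks), "\n")
  invisible(x)
}

#' Presence flags of a pillar set as an n x G x 3 logical array
#' @param ps a [pillar_set()].
#' @return logical array `[pillar, genome, slot]`.
#' @export
presence_array <- function(ps) {
  stopifnot(inherits(ps, "pillar_set"))
  arr <- array(FALSE, c(ps$n, length(ps$genomes), 3L),
               dimnames = list(NULL, ps$genomes, paste0("slot", 1:3)))
  for (s in 1:3) arr[, , s] <- bitwAnd(ps$pattern, c(1L, 2L, 4L)[s]) > 0
  arr
}

#' Read and write pillar tables
#'
#' The on-disk format is a TSV with columns `pillar_id`, `order_index`,
#' `anchor`, then for every genome `g` the columns `g.slot1_gene`,
#' `g.slot1_present`, `g.slot2_gene`, `g.slot2_present`, `g.slot3_gene`,
#' `g.slot3_present`, `g.break` (0/1).
#'
#' @param ps a [pillar_set()].
#' @param path file path.
#' @return `read_pillars()` returns a [pillar_set()] (rows sorted by
#'   `order_index`); `write_pillars()` returns `path` invisibly.
#' @export
write_pillars <- function(ps, path) {
  stopifnot(inherits(ps, "pillar_set"))
  pres <- presence_array(ps)
  df <- data.frame(pillar_id = ps$ids, order_index = ps$order_index,
                   anchor = ps$anchors, stringsAsFactors = FALSE)
  for (g in seq_along(ps$genomes)) {
    gn <- ps$genomes[g]
    for (s in 1:3) {
      gene <- if (!is.null(ps$genes)) ps$genes[[g]][, s] else
        ifelse(pres[, g, s], sprintf("%s_p%d_t%d", gn, seq_len(ps$n), s), "")
      gene[!pres[, g, s]] <- ""
      df[[paste0(gn, ".slot", s, "_gene")]] <- gene
      df[[paste0(gn, ".slot", s, "_present")]] <- as.integer(pres[, g, s])
    }
    df[[paste0(gn, ".break")]] <- as.integer(ps$breaks[, g])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pillars
#' @export
read_pillars <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("pillar_id", "order_index", "anchor")
  if (!all(need %in% names(df))) {
    stop("pillar table must have columns ", paste(need, collapse = ", "))
  }
  df <- df[order(df$order_index), , drop = FALSE]
  brk_cols <- grep("\\.break$", names(df), value = TRUE)
  genomes <- sub("\\.break$", "", brk_cols)
  if (!length(genomes)) stop("no per-genome columns found")
  n <- nrow(df)
  pattern <- matrix(0L, n, length(genomes))
  breaks <- matrix(FALSE, n, length(genomes))
  genes <- vector("list", length(genomes))
  for (g in seq_along(genomes)) {
    gn <- genomes[g]
    gm <- matrix("", n, 3L)
    for (s in 1:3) {
      pres <- df[[paste0(gn, ".slot", s, "_present")]] != 0
      pattern[, g] <- pattern[, g] + as.integer(pres) * c(1L, 2L, 4L)[s]
      gm[, s] <- as.character(df[[paste0(gn, ".slot", s, "_gene")]])
    }
    breaks[, g] <- df[[paste0(gn, ".break")]] != 0
    genes[[g]] <- gm
  }
  pillar_set(pattern, genomes = genomes, breaks = breaks,
             ids = df$pillar_id, anchors = df$anchor, genes = genes)
}

#' Reorder the pillars of a set
#'
#' @param ps a [pillar_set()].
#' @param ordering integer permutation of `1:n` giving the new pillar
#'   sequence.
#' @param breaks how to set break flags in the new order: `"drop"` (no
#'   flags; the default, since flags refer to adjacency in the old order)
#'   or `"keep"` (carry the old flags along with the rows).
#' @return a reordered [pillar_set()].
#' @export
reorder_pillars <- function(ps, ordering, breaks = c("drop", "keep")) {
  stopifnot(inherits(ps, "pillar_set"))
  breaks <- match.arg(breaks)
  ordering <- as.integer(ordering)
  if (length(ordering) != ps$n || !identical(sort(ordering), seq_len(ps$n))) {
    stop("ordering must be a permutation of 1:n")
  }
  newbr <- if (breaks == "keep") ps$breaks[ordering, , drop = FALSE] else
    matrix(FALSE, ps$n, length(ps$genomes))
  pillar_set(ps$pattern[ordering, , drop = FALSE], genomes = ps$genomes,
             breaks = newbr, ids = ps$ids[ordering],
             anchors = ps$anchors[ordering],
             genes = if (!is.null(ps$genes)) {
               lapply(ps$genes, function(m) m[ordering, , drop = FALSE])
             })
}
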
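#' The seven-state copy-number state space
#'
#' After a whole-genome triplication every ancestral locus starts with one
#' gene copy from each of the three parental subgenomes (LF = 1, MF1 = 2,
#' MF2 = 3).  Losses remove copies one at a time and a locus always keeps at
#' least one copy, giving seven states: the triplicated state `T`, three
#' duplicated states `D12`, `D13`, `D23` and three single-copy states `S1`,
#' `S2`, `S3`.  The index of each state name in [state_names()] is the
#' canonical state index used throughout the package.
#'
#' @return `state_names()` returns the seven state labels in canonical
#'   order; `state_members()` returns a list of integer vectors giving the
#'   surviving subgenomes of each state.
#' @examples
#' state_names()
#' state_members()[["D23"]]
#' @export
state_names <- function() {
  c("T", "D12", "D13", "D23", "S1", "S2", "S3")
}

#' @rdname state_names
#' @export
state_members <- function() {
  list(
    T   = c(1L, 2L, 3L),
    D12 = c(1L, 2L),
    D13 = c(1L, 3L),
    D23 = c(2L, 3L),
    S1  = 1L,
    S2  = 2L,
    S3  = 3L
  )
}

#' Number of states (7)
#' @noRd
n_states <- function() 7L

#' Map a set of surviving subgenomes to its state index
#' @param members integer vector, nonempty subset of 1:3
#' @return integer state index in 1..7
#' @noRd
state_from_members <- function(members) {
  members <- sort(unique(as.integer(members)))
  stopifnot(length(members) >= 1L, all(members %in% 1:3))
  idx <- which(vapply(state_members(), function(m) identical(m, members),
                      logical(1)))
  as.integer(idx)
}

#' The six permutations of three syntenic tracks onto three subgenomes
#'
#' Row `p` of the returned matrix maps track slot `s` (column) to subgenome
#' `perm[p, s]`.  The row order is fixed and shared by every function that
#' indexes orthology permutations.
#'
#' @return a 6 x 3 integer matrix.
#' @examples
#' track_permutations()
#' @export
track_permutations <- function() {
  m <- matrix(c(
    1L, 2L, 3L,
    1L, 3L, 2L,
    2L, 1L, 3L,
    2L, 3L, 1L,
    3L, 1L, 2L,
    3L, 2L, 1L
  ), nrow = 6L, byrow = TRUE)
  colnames(m) <- paste0("slot", 1:3)
  m
}

#' Copy-number state implied by a presence pattern under a permutation
#'
#' A pillar records, for one genome, which of its three track slots hold a
#' surviving gene.  Given a hidden permutation assigning slots to
#' subgenomes, the set of surviving subgenomes - and hence the state of the
#' loss chain at that tip - is determined.
#'
#' @param present logical or 0/1 vector of length 3: is slot s occupied?
#' @param perm integer vector of length 3 mapping slot -> subgenome, or a
#'   single integer row index into [track_permutations()].
#' @return integer state index (1..7); see [state_names()].
#' @examples
#' tip_state(c(1, 1, 1), 1L)                 # "T" whatever the permutation
#' tip_state(c(0, 1, 0), c(2, 1, 3))         # slot 2 -> subgenome 1: "S1"
#' @export
tip_state <- function(present, perm) {
  present <- as.logical(present)
  stopifnot(length(present) == 3L)
  if (!any(present)) {
    stop("a pillar must have at least one present track slot per genome")
  }
  if (length(perm) == 1L) {
    perm <- track_permutations()[as.integer(perm), ]
  }
  stopifnot(length(perm) == 3L, setequal(perm, 1:3))
  state_from_members(perm[present])
}

# Precomputed table: rows = presence-pattern mask (1..7, bit s = slot s
# present), cols = permutation index (1..6); entries = state index.
tip_state_table <- function() {
  perms <- track_permutations()
  tab <- matrix(NA_integer_, nrow = 7L, ncol = 6L)
  for (mask in 1:7) {
    present <- as.logical(bitwAnd(mask, c(1L, 2L, 4L)))
    for (p in 1:6) {
      tab[mask, p] <- tip_state(present, perms[p, ])
    }
  }
  tab
}

#' Presence-pattern mask (1..7) from three presence flags
#' @noRd
pattern_mask <- function(present) {
  present <- as.logical(present)
  sum(c(1L, 2L, 4L)[present])
}
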
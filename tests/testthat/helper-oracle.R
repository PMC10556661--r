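# Independent brute-force oracle for series detection: enumerate every
# contiguous window that starts and ends on a class member and contains at
# most one internal non-member, and report the best member count (and, for
# structural checks, the maximal windows themselves). Deliberately written
# as window enumeration so it shares no code path with maximal_runs().

oracle_best_length <- function(member) {
  member <- as.logical(member)
  if (!any(member)) return(0L)
  idx <- which(member)
  cm <- cumsum(member)
  k <- length(idx)
  a <- rep(seq_len(k), times = k)
  b <- rep(seq_len(k), each = k)
  keep <- b >= a
  a <- a[keep]; b <- b[keep]
  members <- cm[idx[b]] - cm[idx[a]] + 1L
  width <- idx[b] - idx[a] + 1L
  valid <- (width - members) <= 1L
  max(members[valid])
}

oracle_maximal_windows <- function(member) {
  member <- as.logical(member)
  n <- length(member)
  wins <- list()
  for (i in seq_len(n)) {
    if (!member[i]) next
    for (j in i:n) {
      if (!member[j]) next
      mem <- sum(member[i:j])
      if ((j - i + 1L) - mem <= 1L) {
        wins[[length(wins) + 1L]] <- c(i, j, mem)
      }
    }
  }
  if (length(wins) == 0L) {
    return(matrix(integer(0), ncol = 3,
                  dimnames = list(NULL, c("start", "end", "members"))))
  }
  m <- do.call(rbind, wins)
  colnames(m) <- c("start", "end", "members")
  contained <- vapply(seq_len(nrow(m)), function(r) {
    any(m[, "start"] <= m[r, "start"] & m[, "end"] >= m[r, "end"] &
          (m[, "end"] - m[, "start"]) > (m[r, "end"] - m[r, "start"]))
  }, logical(1))
  m[!contained, , drop = FALSE]
}

random_membership <- function(max_len = 30L, n_classes = 5L) {
  len <- sample.int(max_len + 1L, 1L) - 1L
  if (len == 0L) return(logical(0))
  cls <- sample.int(n_classes, len, replace = TRUE)
  cls == sample.int(n_classes, 1L)
}

# tiny scored-transcript builder used across tests: tokens is a character
# vector; scheme defaults to the installed demonstration scheme
demo_scheme <- function() {
  load_scheme(system.file("extdata", "demo_scheme.csv",
                          package = "animalfluency"))
}

make_transcripts <- function(..., ids = NULL) {
  seqs <- list(...)
  if (is.null(ids)) ids <- paste0("p", seq_along(seqs))
  as_transcripts(tibble::tibble(
    participant_id = rep(ids, lengths(seqs)),
    position = unlist(lapply(lengths(seqs), function(k) seq_len(k) - 1L)),
    token = unlist(seqs, use.names = FALSE)
  ))
}
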
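## Knowledge similarity matrices and network summaries.

# plain cosine similarity between rows of a weight matrix
cosine_matrix <- function(w) {
  nrm <- sqrt(rowSums(w^2))
  s <- (w %*% t(w)) / outer(nrm, nrm)
  s[s > 1] <- 1
  s[s < -1] <- -1
  s
}

#' Knowledge matrix from event topic vectors
#'
#' Entry (m, n) is the cosine similarity of the topic vectors of events m
#' and n, yielding the event-by-event knowledge-structure matrix with a full
#' availability mask and unit diagonal.
#'
#' @param event_set an [event_set()] with topic vectors attached.
#' @return a [sim_matrix()] of kind `"knowledge"`.
#' @export
#' @examples
#' es <- event_set(c(0, 10, 20), c(10, 10, 10),
#'                 topics = rbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1)))
#' cosine_knowledge_matrix(es)$values
cosine_knowledge_matrix <- function(event_set) {
  w <- event_set$topics
  if (is.null(w)) stop("event set carries no topic vectors")
  zero <- sqrt(rowSums(w^2)) == 0
  if (any(zero)) {
    stop("zero topic vector for event ",
         paste(event_set$events$event_id[zero], collapse = ", "))
  }
  vals <- cosine_matrix(w)
  dimnames(vals) <- list(event_set$events$event_id,
                         event_set$events$event_id)
  sim_matrix(vals, kind = "knowledge")
}

#' Node degree of a similarity network
#'
#' Treats the similarity matrix as a weighted graph on events and returns,
#' for each event, the mean similarity of all available edges connected to
#' it (off-diagonal masked cells of its row). Events with no available edge
#' get `NA` and are reported in the `flagged` attribute.
#'
#' @param x a [sim_matrix()] (or plain symmetric matrix).
#' @return numeric vector of per-event degrees, with attribute `flagged`.
#' @export
node_degree <- function(x) {
  x <- as_sim(x, kind = "knowledge")
  m <- nrow(x$values)
  if (m < 2) stop("need at least 2 events")
  deg <- vapply(seq_len(m), function(i) {
    keep <- x$mask[i, ] & seq_len(m) != i
    if (!any(keep)) NA_real_ else mean(x$values[i, keep])
  }, numeric(1))
  names(deg) <- rownames(x$values)
  attr(deg, "flagged") <- which(!is.finite(deg))
  deg
}

#' Group-average recalled-knowledge matrix
#'
#' Averages per-student recalled-event similarity matrices cellwise over the
#' students whose masks cover each cell. Cells never jointly recalled by any
#' student have zero contributors and stay unavailable in the result.
#'
#' @param matrices a list of [sim_matrix()] objects (or of `recall_record`s,
#'   whose `$matrix` is used), all of the same dimension.
#' @return a [sim_matrix()] of kind `"recalled"` with attribute
#'   `n_contributors` (count matrix).
#' @export
group_average_recall_matrix <- function(matrices) {
  if (!length(matrices)) stop("need at least one student matrix")
  mats <- lapply(matrices, function(x) {
    if (inherits(x, "recall_record")) x$matrix else as_sim(x, "recalled")
  })
  m <- nrow(mats[[1]]$values)
  acc <- matrix(0, m, m)
  cnt <- matrix(0L, m, m)
  for (sm in mats) {
    stopifnot(nrow(sm$values) == m)
    ok <- sm$mask
    acc[ok] <- acc[ok] + sm$values[ok]
    cnt <- cnt + ok
  }
  vals <- ifelse(cnt > 0, acc / pmax(cnt, 1L), NA_real_)
  out <- sim_matrix(vals, mask = cnt > 0, kind = "recalled")
  attr(out, "n_contributors") <- cnt
  out
}

#' Export a similarity network as an edge list
#'
#' Writes the available off-diagonal upper-triangle cells as a long-format
#' TSV (`from`, `to`, `weight`) for network visualization.
#'
#' @param x a [sim_matrix()].
#' @param path output TSV path.
#' @return the edge-list data frame, invisibly.
#' @export
write_edge_list <- function(x, path) {
  x <- as_sim(x, kind = "knowledge")
  m <- nrow(x$values)
  ids <- rownames(x$values) %||% paste0("E", seq_len(m))
  ut <- which(upper.tri(x$values) & x$mask, arr.ind = TRUE)
  el <- data.frame(from = ids[ut[, 1]], to = ids[ut[, 2]],
                   weight = x$values[ut])
  write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(el)
}
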
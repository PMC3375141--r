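## Indirect associations.
##
## Two genes never mentioned together can still be related through a
## shared partner: A and B coregulate Z (A>Z and B>Z), A and B are
## regulated by a common regulator Z (Z>A and Z>B), or A and B share a
## common binding partner Z (A×Z and B×Z).  These joins are computed
## over the aggregated pair table; they are hypothesis-level links
## (coregulation, e.g., additionally requires coexpression), flagged as
## such on every record.

ASSOCIATION_KINDS <- c("coregulation", "common_regulator",
                       "common_binding_partner")

#' Derive indirect associations from aggregated gene pairs
#'
#' Joins the aggregated pair table through shared partners.
#' Regulation and indirect-regulation edges (both assert regulation,
#' the latter indirectly) feed the coregulation join on their out-edges
#' and the common-regulator join on their in-edges; coregulation-capture
#' seeds feed only the coregulation join; binding edges feed the
#' common-binding-partner join.  Each association lists all shared
#' partners; a partner supported by several edge classes is counted
#' once.
#'
#' @param gp A `gene_pairs` object (see [aggregate_pairs()]), or its
#'   `pairs` data.frame.
#' @return A data.frame of class `indirect_associations` with columns
#'   `kind`, `key_a`, `key_b` (lexicographic, the relation is
#'   symmetric), `n_shared`, `shared` (partner keys, `;`-separated),
#'   `best_edge_score`, `hypothetical` (always `TRUE`).
#' @export
derive_indirect <- function(gp) {
  pairs <- if (inherits(gp, "gene_pairs")) gp$pairs else gp
  captures <- if (inherits(gp, "gene_pairs"))
    gp$evidence[gp$evidence$cls == "coregulation_capture", , drop = FALSE]
  else NULL

  rows <- list()
  emit <- function(kind, a, b, z, score) {
    k <- sort(c(a, b))
    rows[[length(rows) + 1L]] <<-
      data.frame(kind = kind, key_a = k[1], key_b = k[2], shared = z,
                 edge_score = score, stringsAsFactors = FALSE)
  }

  reg <- pairs[pairs$cls %in% c("regulation", "indirect_regulation"), , drop = FALSE]
  bind <- pairs[pairs$cls == "binding", , drop = FALSE]

  ## coregulation: out-edge join A>Z, B>Z
  if (nrow(reg)) {
    for (z in unique(reg$key_b)) {
      e <- reg[reg$key_b == z, , drop = FALSE]
      regs <- unique(e$key_a)
      if (length(regs) < 2L) next
      for (i in seq_len(length(regs) - 1L)) for (j in (i + 1L):length(regs)) {
        sc <- suppressWarnings(max(e$agg_score[e$key_a %in% c(regs[i], regs[j])],
                                   na.rm = TRUE))
        emit("coregulation", regs[i], regs[j], z,
             if (is.finite(sc)) sc else NA_real_)
      }
    }
  }
  ## coregulation seeds from discarded Cause–Cause candidates
  if (!is.null(captures) && nrow(captures)) {
    cap <- captures[!is.na(captures$target), , drop = FALSE]
    if (nrow(cap))
      for (r in seq_len(nrow(cap)))
        emit("coregulation", cap$key_a[r], cap$key_b[r], cap$target[r],
             cap$score[r])
  }
  ## common regulator: in-edge join Z>A, Z>B
  if (nrow(reg)) {
    for (z in unique(reg$key_a)) {
      e <- reg[reg$key_a == z, , drop = FALSE]
      tgts <- unique(e$key_b)
      if (length(tgts) < 2L) next
      for (i in seq_len(length(tgts) - 1L)) for (j in (i + 1L):length(tgts)) {
        sc <- suppressWarnings(max(e$agg_score[e$key_b %in% c(tgts[i], tgts[j])],
                                   na.rm = TRUE))
        emit("common_regulator", tgts[i], tgts[j], z,
             if (is.finite(sc)) sc else NA_real_)
      }
    }
  }
  ## common binding partner: A×Z, B×Z (undirected edges)
  if (nrow(bind)) {
    half <- rbind(data.frame(g = bind$key_a, z = bind$key_b, s = bind$agg_score,
                             stringsAsFactors = FALSE),
                  data.frame(g = bind$key_b, z = bind$key_a, s = bind$agg_score,
                             stringsAsFactors = FALSE))
    for (z in unique(half$z)) {
      e <- half[half$z == z, , drop = FALSE]
      gs <- unique(e$g)
      if (length(gs) < 2L) next
      for (i in seq_len(length(gs) - 1L)) for (j in (i + 1L):length(gs)) {
        sc <- suppressWarnings(max(e$s[e$g %in% c(gs[i], gs[j])], na.rm = TRUE))
        emit("common_binding_partner", gs[i], gs[j], z,
             if (is.finite(sc)) sc else NA_real_)
      }
    }
  }

  if (length(rows) == 0L) {
    out <- data.frame(kind = character(0), key_a = character(0),
                      key_b = character(0), n_shared = integer(0),
                      shared = character(0), best_edge_score = numeric(0),
                      hypothetical = logical(0), stringsAsFactors = FALSE)
    return(structure(out, class = c("indirect_associations", "data.frame")))
  }
  flat <- do.call(rbind, rows)
  gid <- paste(flat$kind, flat$key_a, flat$key_b, sep = "\r")
  out <- do.call(rbind, lapply(split(seq_len(nrow(flat)), gid), function(idx) {
    e <- flat[idx, , drop = FALSE]
    zs <- sort(unique(e$shared))
    data.frame(kind = e$kind[1], key_a = e$key_a[1], key_b = e$key_b[1],
               n_shared = length(zs), shared = paste(zs, collapse = ";"),
               best_edge_score = if (all(is.na(e$edge_score))) NA_real_
                                 else max(e$edge_score, na.rm = TRUE),
               hypothetical = TRUE, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out[order(out$kind, out$key_a, out$key_b), , drop = FALSE],
            class = c("indirect_associations", "data.frame"))
}

#' Rank indirect associations
#'
#' Orders associations by the number of shared partners (descending),
#' breaking ties by the best underlying edge score (descending) and
#' then by lexicographic keys, so the order is deterministic across
#' runs.
#'
#' @param assocs An `indirect_associations` data.frame.
#' @return The reordered data.frame.
#' @export
rank_associations <- function(assocs) {
  sc <- assocs$best_edge_score
  sc[is.na(sc)] <- -Inf
  out <- assocs[order(-assocs$n_shared, -sc, assocs$key_a, assocs$key_b,
                      assocs$kind), , drop = FALSE]
  rownames(out) <- NULL
  out
}
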
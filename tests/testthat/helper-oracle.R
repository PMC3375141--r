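# Independent oracles used by the refinement and pair-extraction tests.

REG3 <- c("regulation", "positive_regulation", "negative_regulation")

# Literal nine-entry polarity table, written out row by row.
table_compose <- function(outer, nested) {
  key <- paste(outer, nested)
  switch(key,
    "positive_regulation positive_regulation" = "positive_regulation",
    "positive_regulation regulation"          = "positive_regulation",
    "regulation positive_regulation"          = "positive_regulation",
    "negative_regulation negative_regulation" = "positive_regulation",
    "regulation regulation"                   = "regulation",
    "negative_regulation regulation"          = "negative_regulation",
    "negative_regulation positive_regulation" = "negative_regulation",
    "regulation negative_regulation"          = "negative_regulation",
    "positive_regulation negative_regulation" = "negative_regulation",
    stop("not a regulation pair"))
}

# Brute-force rewriter: at every pass, list all redex positions in
# preorder, apply only the first, and rescan from the root; the
# one-polarity-change budget is enforced per whole structure.
brute_refine <- function(tree) {
  changes <- 0L
  repeat {
    pos <- find_first_redex(tree)
    if (is.null(pos)) break
    res <- apply_at(tree, pos, changes)
    tree <- res$tree
    changes <- res$changes
  }
  list(structure = tree, changes = changes)
}

# Preorder path (vector of child indices) of the first redex, or NULL.
find_first_redex <- function(node, path = integer(0)) {
  if (node$kind != "event") return(NULL)
  if (node$type %in% REG3) {
    ti <- which(node$roles == "Theme")
    th <- node$children[[ti]]
    if (th$kind == "event" && th$type %in% REG3 && !any(th$roles == "Cause"))
      return(path)
  }
  for (k in seq_along(node$children)) {
    found <- find_first_redex(node$children[[k]], c(path, k))
    if (!is.null(found)) return(found)
  }
  NULL
}

apply_at <- function(tree, path, changes) {
  rebuild <- function(node, path) {
    if (length(path) == 0L) {
      ti <- which(node$roles == "Theme")
      nested <- node$children[[ti]]
      res <- table_compose(node$type, nested$type)
      if (res != node$type) {
        if (changes >= 1L) res <- "regulation" else changes <<- changes + 1L
      }
      node$type <- res
      node$children[[ti]] <- nested$children[[which(nested$roles == "Theme")]]
      return(node)
    }
    node$children[[path[1]]] <- rebuild(node$children[[path[1]]], path[-1])
    node
  }
  list(tree = rebuild(tree, path), changes = changes)
}

# ---- exhaustive structure enumeration (depth <= 3, <= 4 genes) -------------

# Shapes are trees whose leaves are gene slots; placeholder symbols are
# assigned afterwards.  gene_slot() marks a slot.
gene_slot <- function() ev_gene("?")

n_slots <- function(node) {
  if (node$kind == "gene") return(1L)
  sum(vapply(node$children, n_slots, integer(1)))
}

# All event shapes of exact depth 1.
shapes_depth1 <- function() {
  out <- list(ev_event("phosphorylation", "Theme", list(gene_slot())),
              ev_event("binding", c("Theme", "Theme"),
                       list(gene_slot(), gene_slot())),
              ev_event("binding", rep("Theme", 3),
                       list(gene_slot(), gene_slot(), gene_slot())))
  for (ty in REG3) {
    out <- c(out,
             list(ev_event(ty, "Theme", list(gene_slot())),
                  ev_event(ty, c("Cause", "Theme"),
                           list(gene_slot(), gene_slot()))))
  }
  out
}

# All regulation shapes of exact depth d given shapes of depth < d.
shapes_depth_reg <- function(d, below) {
  shallower <- unlist(below[seq_len(d - 1L)], recursive = FALSE)
  exact <- below[[d - 1L]]
  theme_opts <- c(list(gene_slot()), shallower)
  cause_opts <- c(list(NULL, gene_slot()), shallower)
  out <- list()
  for (ty in REG3) for (th in theme_opts) for (ca in cause_opts) {
    depth_th <- if (th$kind == "gene") 0L else tree_depth_pub(th)
    depth_ca <- if (is.null(ca) || ca$kind == "gene") 0L else tree_depth_pub(ca)
    if (max(depth_th, depth_ca) != d - 1L) next
    roles <- "Theme"; children <- list(th)
    if (!is.null(ca)) { roles <- c("Cause", roles); children <- c(list(ca), children) }
    sh <- ev_event(ty, roles, children)
    if (n_slots(sh) > 4L) next
    out <- c(out, list(sh))
  }
  out
}

tree_depth_pub <- function(node) {
  if (node$kind == "gene") return(0L)
  1L + max(c(0L, vapply(node$children, tree_depth_pub, integer(1))))
}

# All valid event shapes up to depth 3 with at most 4 gene slots.
enumerate_shapes <- function(max_depth = 3) {
  below <- list(shapes_depth1())
  if (max_depth >= 2) below[[2]] <- shapes_depth_reg(2L, below)
  if (max_depth >= 3) below[[3]] <- shapes_depth_reg(3L, below)
  unlist(below, recursive = FALSE)
}

# Fill gene slots with distinct placeholder symbols in traversal order.
fill_slots <- function(shape, symbols) {
  i <- 0L
  walk <- function(node) {
    if (node$kind == "gene") {
      i <<- i + 1L
      node$symbol <- symbols[i]
      return(node)
    }
    node$children <- lapply(node$children, walk)
    node
  }
  walk(shape)
}

# Brute-force triple-loop association join over an aggregated pair
# table (no capture seeds), independent of derive_indirect().
brute_join <- function(pairs) {
  genes <- sort(unique(c(pairs$key_a, pairs$key_b)))
  reg <- pairs[pairs$cls %in% c("regulation", "indirect_regulation"), , drop = FALSE]
  bnd <- pairs[pairs$cls == "binding", , drop = FALSE]
  has_reg <- function(a, z) any(reg$key_a == a & reg$key_b == z)
  has_bind <- function(a, z) any((bnd$key_a == a & bnd$key_b == z) |
                                 (bnd$key_a == z & bnd$key_b == a))
  rows <- list()
  for (a in genes) for (b in genes) {
    if (a >= b) next
    for (kind in c("coregulation", "common_regulator", "common_binding_partner")) {
      zs <- character(0)
      for (z in genes) {
        hit <- switch(kind,
          coregulation = has_reg(a, z) && has_reg(b, z),
          common_regulator = has_reg(z, a) && has_reg(z, b),
          common_binding_partner = has_bind(a, z) && has_bind(b, z))
        if (hit) zs <- c(zs, z)
      }
      zs <- setdiff(zs, c(a, b))
      # partners equal to an endpoint can arise for bindings; keep the
      # same convention as the package (partner may be any gene)
      zs <- sort(unique(zs))
      if (length(zs))
        rows[[length(rows) + 1L]] <- data.frame(
          kind = kind, key_a = a, key_b = b, n_shared = length(zs),
          shared = paste(zs, collapse = ";"), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(kind = character(0), key_a = character(0),
                      key_b = character(0), n_shared = integer(0),
                      shared = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
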
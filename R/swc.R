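# Direction vectors used when laying sections out in 3D for SWC export.
swc_dir <- function(kind) switch(kind,
  soma = c(1, 0, 0), axon_main = c(1, 0, 0), dendrite = c(-1, 0, 0),
  axon_collateral = c(0, 1, 0))

#' Export a morphology to SWC format
#'
#' Standard 7-column SWC (index, type, x, y, z, radius, parent) with type
#' codes 1 = soma, 2 = axon, 3 = dendrite. Collaterals are written as axon
#' (type 2); their identity is carried in a sidecar mapping returned
#' invisibly (section id -> SWC indices) and accepted back by [read_swc()].
#' Sections are laid out as straight chains (axon along +x, dendrite along
#' -x, collaterals along +y), one sample per compartment boundary.
#'
#' @param sections list of [section()] objects (or a `cable_model`).
#' @param path output file.
#' @return invisibly, the collateral sidecar mapping.
#' @export
write_swc <- function(sections, path) {
  if (inherits(sections, "cable_model")) sections <- sections$sections
  validate_sections(sections)
  ids <- vapply(sections, `[[`, "", "id")
  rows <- list(); node_of_sec <- list(); origin <- list(); coll <- list()
  nid <- 0L
  for (s in sections) {
    dirv <- swc_dir(s$kind)
    type <- switch(s$kind, soma = 1L, dendrite = 3L, 2L)
    if (is.na(s$parent)) {
      start <- c(0, 0, 0); pnode <- -1L
    } else {
      psec <- match(s$parent, ids)
      pn <- node_of_sec[[psec]]
      k <- max(1L, min(length(pn), ceiling(s$connect_at * length(pn))))
      pnode <- pn[k]
      start <- rows[[pnode]][3:5]
    }
    n <- s$n_compartments
    nodes <- integer(n + ifelse(pnode < 0, 1L, 0L))
    if (pnode < 0) {                       # root: emit the starting sample
      nid <- nid + 1L
      rows[[nid]] <- c(nid, type, start, s$diameter_um / 2, -1L)
      nodes[1] <- nid; prev <- nid; off <- 1L
    } else { prev <- pnode; off <- 0L }
    for (ci in seq_len(n)) {
      nid <- nid + 1L
      pos <- start + dirv * s$length_um * ci / n
      rows[[nid]] <- c(nid, type, pos, s$diameter_um / 2, prev)
      nodes[ci + off] <- nid
      prev <- nid
    }
    node_of_sec[[match(s$id, ids)]] <- nodes
    if (s$kind == "axon_collateral") coll[[s$id]] <- nodes
  }
  m <- do.call(rbind, rows)
  writeLines(c("# SWC export; type codes 1=soma 2=axon 3=dendrite",
               apply(m, 1, function(r) paste(format(r, trim = TRUE), collapse = " "))),
             path)
  invisible(coll)
}

#' Read an SWC morphology into sections
#'
#' Maximal unbranched runs of same-type samples become cylindrical sections
#' (length = summed inter-sample distances, diameter = 2 x mean radius).
#' Sections whose id appears in `collateral_ids` (or whose first SWC index is
#' listed there) are marked `axon_collateral`; axial resistivities are
#' assigned per kind.
#'
#' @param path SWC file.
#' @param dx_um target compartment length for discretization.
#' @param ra per-kind axial resistivity, Ohm cm.
#' @param collateral_ids SWC sample indices belonging to collaterals (the
#'   sidecar mapping of [write_swc()]).
#' @return list of [section()] objects.
#' @export
read_swc <- function(path, dx_um = 5,
                     ra = c(soma = 150, axon_main = 80, dendrite = 150,
                            axon_collateral = 300),
                     collateral_ids = integer(0)) {
  collateral_ids <- unlist(collateral_ids, use.names = FALSE)
  d <- read.table(path, comment.char = "#",
                  col.names = c("id", "type", "x", "y", "z", "r", "parent"))
  if (!all(d$type %in% c(1, 2, 3)))
    stop("unsupported SWC type code(s): ",
         paste(setdiff(unique(d$type), 1:3), collapse = ", "))
  idx <- match(d$parent, d$id)                   # NA for roots
  nchild <- tabulate(idx[!is.na(idx)], nbins = nrow(d))
  kind_of <- function(i) {
    if (d$type[i] == 1) "soma"
    else if (d$type[i] == 3) "dendrite"
    else if (d$id[i] %in% collateral_ids) "axon_collateral" else "axon_main"
  }
  seg_len <- function(i, j)
    sqrt(sum((c(d$x[i], d$y[i], d$z[i]) - c(d$x[j], d$y[j], d$z[j]))^2))
  children <- split(seq_len(nrow(d)), factor(idx, levels = seq_len(nrow(d))))
  sec_of_node <- integer(nrow(d))
  sections <- list()
  root <- which(is.na(idx))
  if (length(root) != 1) stop("SWC must contain exactly one root sample")
  queue <- list(list(start = root, parent_sec = NA_integer_))
  while (length(queue)) {
    job <- queue[[1]]; queue <- queue[-1]
    run <- job$start
    repeat {
      last <- run[length(run)]
      ch <- children[[last]]
      if (length(ch) == 1 && kind_of(ch) == kind_of(last) && nchild[last] == 1) {
        run <- c(run, ch)
      } else break
    }
    k <- kind_of(run[1])
    L <- if (length(run) > 1)
      sum(vapply(seq_len(length(run) - 1),
                 function(q) seg_len(run[q], run[q + 1]), 0))
    else 2 * mean(d$r[run])                       # lone soma sample: sphere
    if (!is.na(idx[run[1]])) L <- L + seg_len(idx[run[1]], run[1])
    si <- length(sections) + 1L
    sections[[si]] <- section(
      id = sprintf("%s_%d", k, si),
      parent = if (is.na(job$parent_sec)) NA else sections[[job$parent_sec]]$id,
      length_um = max(L, 0.1), diameter_um = max(2 * mean(d$r[run]), 0.05),
      ra_ohm_cm = ra[[k]],
      n_compartments = max(1L, round(max(L, 0.1) / dx_um)), kind = k)
    sec_of_node[run] <- si
    last <- run[length(run)]
    nexts <- children[[last]]
    nexts <- setdiff(nexts, run)
    for (nx in nexts) queue[[length(queue) + 1L]] <- list(start = nx, parent_sec = si)
  }
  sections
}
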
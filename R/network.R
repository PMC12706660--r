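#' Blood fluid properties
#'
#' Blood is treated as an incompressible Newtonian fluid. Defaults are the
#' standard haemodynamic values: density 1050 kg/m^3 and dynamic viscosity
#' 0.0035 Pa.s.
#'
#' @param density fluid density, kg/m^3.
#' @param viscosity dynamic viscosity, Pa.s.
#' @return an object of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 1050, viscosity = 0.0035) {
  if (!is.numeric(density) || length(density) != 1L || density <= 0)
    stop("density must be a single positive number")
  if (!is.numeric(viscosity) || length(viscosity) != 1L || viscosity <= 0)
    stop("viscosity must be a single positive number")
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

# Poiseuille resistance and plug-flow inertance of a cylindrical segment
segment_resistance <- function(length, radius, viscosity) {
  8 * viscosity * length / (pi * radius^4)
}
segment_inertance <- function(length, radius, density) {
  density * length / (pi * radius^2)
}

#' Construct an arterial network
#'
#' An arterial network is a directed tree of cylindrical vessel segments with
#' a single cardiac inlet node, a set of labelled outlet nodes (each of which
#' receives a three-element Windkessel boundary in simulation), and optional
#' named graft sites where an LVAD outflow cannula can be attached.
#'
#' @param segments data frame with columns `id`, `from`, `to`, `length` (m),
#'   `radius` (m), and optionally `group` (free-text tag such as `"trunk"`).
#' @param inlet_node label of the cardiac inlet node.
#' @param outlets data frame with columns `node`, `name`: terminal nodes and
#'   the artery name attached to each.
#' @param graft_sites named character vector of node labels, e.g.
#'   `c(right_axillary = "r_axillary")`.
#' @param fluid a [fluid_properties()] object.
#' @return an object of class `arterial_network`. Derived per-segment
#'   Poiseuille `resistance` (Pa.s/m^3) and `inertance` (Pa.s^2/m^3) columns
#'   are added to `segments`.
#' @seealso [build_default_network()] for the default aortic tree.
#' @export
arterial_network <- function(segments, inlet_node, outlets,
                             graft_sites = character(), fluid = fluid_properties()) {
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  required <- c("id", "from", "to", "length", "radius")
  if (!all(required %in% names(segments)))
    stop("segments must have columns: ", paste(required, collapse = ", "))
  if (is.null(segments$group)) segments$group <- "branch"
  if (anyDuplicated(segments$id))
    stop("validation error: duplicate segment ids")
  if (any(segments$length <= 0) || any(segments$radius <= 0))
    stop("segment length and radius must be strictly positive")

  outlets <- as.data.frame(outlets, stringsAsFactors = FALSE)
  if (!all(c("node", "name") %in% names(outlets)))
    stop("outlets must have columns node, name")
  if (anyDuplicated(outlets$name))
    stop("validation error: duplicate outlet names")

  nodes <- unique(c(segments$from, segments$to))
  if (!inlet_node %in% nodes) stop("inlet node not present in segment table")
  if (!all(outlets$node %in% nodes)) stop("outlet node not present in network")
  if (length(graft_sites) && !all(graft_sites %in% nodes))
    stop("lookup error: graft site node not present in network")

  # tree check: |segments| = |nodes| - 1 and connected, no cycles
  if (nrow(segments) != length(nodes) - 1L)
    stop("topology error: segment/node count violates the tree property ",
         "(cycle or disconnected component)")
  adj <- split(c(segments$to, segments$from), c(segments$from, segments$to))
  seen <- character()
  frontier <- inlet_node
  while (length(frontier)) {
    seen <- c(seen, frontier)
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, seen)
  }
  if (!setequal(seen, nodes))
    stop("topology error: network is not connected")

  segments$resistance <- segment_resistance(segments$length, segments$radius,
                                            fluid$viscosity)
  segments$inertance <- segment_inertance(segments$length, segments$radius,
                                          fluid$density)

  net <- structure(
    list(segments = segments, inlet_node = inlet_node, outlets = outlets,
         graft_sites = graft_sites, fluid = fluid, lvad = NULL),
    class = "arterial_network")
  net
}

#' @export
print.arterial_network <- function(x, ...) {
  cat("Arterial network:", nrow(x$segments), "segments,",
      length(network_nodes(x)), "nodes,", nrow(x$outlets), "outlets\n")
  cat("  inlet:", x$inlet_node, "\n")
  if (length(x$graft_sites))
    cat("  graft sites:", paste(names(x$graft_sites), collapse = ", "), "\n")
  if (!is.null(x$lvad))
    cat("  LVAD graft at", x$lvad$site, "-",
        format(as_lpm(x$lvad$flow_rate)), "L/min\n")
  invisible(x)
}

#' Node labels of a network
#' @param network an `arterial_network`.
#' @return character vector of node labels.
#' @export
network_nodes <- function(network) {
  unique(c(network$segments$from, network$segments$to))
}

#' Outlet names of a network
#' @param network an `arterial_network`.
#' @return character vector of outlet (artery) names in table order.
#' @export
outlet_names <- function(network) network$outlets$name

# parent map: for each node, the segment row index arriving from the inlet side.
# Built by BFS from the inlet; directedness of stored segments is ignored.
.parent_segments <- function(network) {
  seg <- network$segments
  parent <- setNames(rep(NA_integer_, length(network_nodes(network))),
                     network_nodes(network))
  frontier <- network$inlet_node
  visited <- frontier
  while (length(frontier)) {
    nxt <- character()
    for (nd in frontier) {
      rows <- which((seg$from == nd | seg$to == nd))
      for (r in rows) {
        other <- if (seg$from[r] == nd) seg$to[r] else seg$from[r]
        if (!other %in% visited) {
          parent[other] <- r
          visited <- c(visited, other)
          nxt <- c(nxt, other)
        }
      }
    }
    frontier <- nxt
  }
  parent
}

#' Cumulative Poiseuille resistance along the inlet-to-node path
#'
#' Sums per-segment Poiseuille resistances along the unique tree path from the
#' cardiac inlet to `node`. Used by the calibration to discount upstream
#' viscous losses when sizing outlet Windkessel resistances.
#'
#' @param network an `arterial_network`.
#' @param node target node label (may be a vector).
#' @return numeric vector of path resistances, Pa.s/m^3.
#' @export
path_resistance <- function(network, node) {
  parent <- .parent_segments(network)
  seg <- network$segments
  vapply(node, function(nd) {
    if (!nd %in% names(parent)) stop("lookup error: unknown node ", nd)
    acc <- 0
    cur <- nd
    while (cur != network$inlet_node) {
      r <- parent[[cur]]
      acc <- acc + seg$resistance[r]
      cur <- if (seg$from[r] == cur) seg$to[r] else seg$from[r]
    }
    acc
  }, numeric(1))
}

# default geometry of the synthetic adult aortic tree (lengths/radii in mm).
# Radii follow literature-typical adult dimensions; only relative flow
# redistribution is claimed, not patient-specific anatomy.
.default_geometry <- function() {
  g <- rbind(
    # id,                 from,            to,                     len, rad, group
    c("asc_aorta",        "inlet",         "arch_bct",              60, 12.5, "trunk"),
    c("arch_a",           "arch_bct",      "arch_lcc",              25, 11.5, "trunk"),
    c("arch_b",           "arch_lcc",      "arch_lsc",              25, 11.0, "trunk"),
    c("desc_thoracic",    "arch_lsc",      "abd_celiac",           200, 10.0, "trunk"),
    c("abd_suprarenal_a", "abd_celiac",    "abd_sma",               20,  8.5, "trunk"),
    c("abd_suprarenal_b", "abd_sma",       "abd_renal",             30,  8.5, "trunk"),
    c("abd_infrarenal_a", "abd_renal",     "abd_ima",               60,  7.0, "trunk"),
    c("abd_infrarenal_b", "abd_ima",       "aortic_bif",            40,  7.0, "trunk"),
    c("brachiocephalic",  "arch_bct",      "bct_div",               40,  6.5, "branch"),
    c("r_subclavian",     "bct_div",       "r_axillary",            60,  4.5, "branch"),
    c("r_axillary",       "r_axillary",    "out_r_subclavian",      80,  3.5, "branch"),
    c("r_carotid",        "bct_div",       "out_r_carotid",        150,  3.5, "branch"),
    c("l_carotid",        "arch_lcc",      "out_l_carotid",        150,  3.5, "branch"),
    c("l_subclavian",     "arch_lsc",      "out_l_subclavian",     120,  4.5, "branch"),
    c("celiac",           "abd_celiac",    "out_celiac",            30,  4.0, "branch"),
    c("sma",              "abd_sma",       "out_sma",               50,  4.0, "branch"),
    c("l_renal",          "abd_renal",     "out_l_renal",           40,  3.0, "branch"),
    c("r_renal",          "abd_renal",     "out_r_renal",           40,  3.0, "branch"),
    c("ima",              "abd_ima",       "out_ima",               40,  2.0, "branch"),
    c("r_common_iliac",   "aortic_bif",    "r_iliac_div",           60,  5.0, "branch"),
    c("l_common_iliac",   "aortic_bif",    "l_iliac_div",           60,  5.0, "branch"),
    c("r_internal_iliac", "r_iliac_div",   "out_r_internal_iliac",  50,  3.0, "branch"),
    c("l_internal_iliac", "l_iliac_div",   "out_l_internal_iliac",  50,  3.0, "branch"),
    c("r_external_iliac", "r_iliac_div",   "r_femoral_div",         80,  4.5, "branch"),
    c("l_external_iliac", "l_iliac_div",   "l_femoral_div",         80,  4.5, "branch"),
    c("r_profunda",       "r_femoral_div", "out_r_profunda",        60,  3.0, "branch"),
    c("l_profunda",       "l_femoral_div", "out_l_profunda",        60,  3.0, "branch"),
    c("r_femoral_prox",   "r_femoral_div", "r_femoral",             40,  4.0, "branch"),
    c("r_femoral_dist",   "r_femoral",     "out_r_femoral",        100,  4.0, "branch"),
    c("l_femoral",        "l_femoral_div", "out_l_femoral",        140,  4.0, "branch")
  )
  data.frame(id = g[, 1], from = g[, 2], to = g[, 3],
             length = as.numeric(g[, 4]) * 1e-3,
             radius = as.numeric(g[, 5]) * 1e-3,
             group = g[, 6], stringsAsFactors = FALSE)
}

# the 15 outlet rows, in the order of the reference flow-division table
.default_outlets <- function() {
  data.frame(
    node = c("out_r_subclavian", "out_r_carotid", "out_l_carotid",
             "out_l_subclavian", "out_r_internal_iliac", "out_l_internal_iliac",
             "out_r_profunda", "out_r_femoral", "out_l_profunda",
             "out_l_femoral", "out_ima", "out_sma", "out_celiac",
             "out_l_renal", "out_r_renal"),
    name = c("Right subclavian artery", "Right common carotid artery",
             "Left common carotid artery", "Left subclavian artery",
             "Right internal iliac artery", "Left internal iliac artery",
             "Right profunda femoris artery", "Right femoral artery",
             "Left profunda femoris artery", "Left femoral artery",
             "Inferior mesenteric artery", "Superior mesenteric artery",
             "Celiac trunk", "Left renal artery", "Right renal artery"),
    stringsAsFactors = FALSE)
}

#' Build the default synthetic aortic tree
#'
#' Constructs the package's synthetic systemic arterial tree: ascending aorta,
#' arch, descending thoracic aorta, supra- and infrarenal abdominal aorta and
#' iliac bifurcation, with fifteen named branch outlets (subclavian, carotid,
#' celiac, mesenteric, renal, iliac and femoral territories). The right
#' axillary and right femoral nodes are registered as LVAD graft sites; each
#' sits one segment proximal to the same-named outlet, so the cannulated
#' artery keeps its own Windkessel outlet.
#'
#' Dimensions are literature-typical adult values (ascending aorta radius
#' 12.5 mm tapering to 7 mm infrarenally, 3.5-4.5 mm arch branches, 4 mm
#' femoral arteries) and can be overridden per segment.
#'
#' @param overrides optional named list of per-segment geometry overrides,
#'   e.g. `list(desc_thoracic = list(radius = 0.011))`; lengths/radii in m.
#' @param fluid a [fluid_properties()] object.
#' @return an `arterial_network` with 30 segments, 31 nodes and 15 outlets.
#' @examples
#' net <- build_default_network()
#' outlet_names(net)
#' @export
build_default_network <- function(overrides = NULL, fluid = fluid_properties()) {
  geo <- .default_geometry()
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("overrides must be a named list keyed by segment id")
    for (id in names(overrides)) {
      i <- match(id, geo$id)
      if (is.na(i)) stop("lookup error: unknown segment id in overrides: ", id)
      ov <- overrides[[id]]
      for (fld in names(ov)) {
        if (!fld %in% c("length", "radius"))
          stop("only length and radius can be overridden (segment ", id, ")")
        val <- ov[[fld]]
        if (!is.numeric(val) || length(val) != 1L || val <= 0)
          stop("override ", fld, " for segment ", id,
               " must be a single positive number")
        geo[[fld]][i] <- val
      }
    }
  }
  arterial_network(
    segments = geo, inlet_node = "inlet", outlets = .default_outlets(),
    graft_sites = c(right_axillary = "r_axillary", right_femoral = "r_femoral"),
    fluid = fluid)
}

#' Identify aortic trunk segments
#'
#' @param network an `arterial_network` built by [build_default_network()]
#'   (or a refinement of it).
#' @param include_ascending include the ascending aorta segment.
#' @return character vector of trunk segment ids.
#' @export
trunk_segments <- function(network, include_ascending = TRUE) {
  ids <- network$segments$id[network$segments$group == "trunk"]
  if (!include_ascending) {
    parent <- attr(network, "parent_segment")
    base <- if (is.null(parent)) ids else parent[ids]
    ids <- ids[!grepl("^asc_aorta", base)]
  }
  ids
}

#' Subdivide segments of a network
#'
#' Splits each listed segment into `factor` serial sub-segments of equal
#' length and unchanged radius. Total Poiseuille resistance and inertance are
#' preserved exactly (both are additive in length), so the refined network
#' represents the same physical geometry at finer axial resolution. Used by
#' [discretization_study()] as the lumped-model analogue of a mesh-refinement
#' study.
#'
#' @param network an `arterial_network` (ungrafted).
#' @param ids segment ids to subdivide; defaults to the aortic trunk.
#' @param factor integer number of sub-segments per listed segment.
#' @return a new `arterial_network`; the attribute `"parent_segment"` maps
#'   each segment id of the refined network to the id it came from.
#' @export
refine_network <- function(network, ids = trunk_segments(network), factor = 2L) {
  stopifnot(factor >= 1L)
  if (!is.null(network$lvad))
    stop("refine the ungrafted network, then re-apply the LVAD graft")
  seg <- network$segments
  out <- list()
  parent_map <- character()
  for (i in seq_len(nrow(seg))) {
    s <- seg[i, ]
    if (s$id %in% ids && factor > 1L) {
      nodes <- c(s$from,
                 paste0(s$id, "_n", seq_len(factor - 1L)),
                 s$to)
      for (k in seq_len(factor)) {
        sub <- s
        sub$id <- paste0(s$id, "_", k)
        sub$from <- nodes[k]
        sub$to <- nodes[k + 1L]
        sub$length <- s$length / factor
        out[[length(out) + 1L]] <- sub
        parent_map[sub$id] <- s$id
      }
    } else {
      out[[length(out) + 1L]] <- s
      parent_map[s$id] <- s$id
    }
  }
  refined <- do.call(rbind, out)[, c("id", "from", "to", "length", "radius", "group")]
  net <- arterial_network(refined, network$inlet_node, network$outlets,
                          network$graft_sites, network$fluid)
  attr(net, "parent_segment") <- parent_map
  net
}

#' Export / import a network segment table
#'
#' Writes (or reads) the plain tabular segment description: one row per
#' segment with id, end nodes, length and radius in metres, and group tag.
#' Derived resistance/inertance columns are recomputed on read.
#'
#' @param network an `arterial_network`.
#' @param path file path of a tab-separated table.
#' @param inlet_node,outlets,graft_sites,fluid passed to [arterial_network()]
#'   on read.
#' @return `read_network_tsv()` returns an `arterial_network`;
#'   `write_network_tsv()` returns `path` invisibly.
#' @export
write_network_tsv <- function(network, path) {
  utils::write.table(
    network$segments[, c("id", "from", "to", "length", "radius", "group")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
read_network_tsv <- function(path, inlet_node, outlets,
                             graft_sites = character(),
                             fluid = fluid_properties()) {
  seg <- utils::read.delim(path, stringsAsFactors = FALSE)
  arterial_network(seg, inlet_node, outlets, graft_sites, fluid)
}
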
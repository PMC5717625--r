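#' Node specification for one local model of the piecewise SEM
#'
#' A node is one response variable of the food-web graph together with the
#' generalized linear mixed model used to estimate its incoming paths:
#' a Poisson (log link) count model with a sampling-effort offset, or a
#' binomial (logit link) model for a bounded score (percentage spinifex
#' cover out of 100, seed index out of 5). Every node carries a single
#' random intercept on the sampling occasion ("trip" for pitfall/vegetation
#' data, "month" for camera data).
#'
#' @param name node identifier (e.g. `"rodents"`).
#' @param family `"poisson"` or `"binomial"`.
#' @param response column holding the response (count, or score in
#'   `[0, denominator]`).
#' @param predictors character vector of predictor terms in model order.
#'   Interactions are written `"a:b"` and count as a single term (a single
#'   path of the graph). Factor predictors must also be listed in `factors`.
#' @param offset column holding the effort for the offset (`log(effort)` is
#'   added to the linear predictor), or `NULL` for binomial nodes.
#' @param random column holding the random-intercept grouping factor.
#' @param denominator binomial denominator (100 for cover, 5 for seed), or
#'   `NULL` for Poisson nodes.
#' @param frame name of the analysis table this node is fitted on
#'   (`"captures"`, `"camera"`, `"vegetation"`).
#' @param factors predictor terms to be treated as categorical.
#' @param z_transform if `TRUE`, numeric predictors are centred and scaled
#'   to unit standard deviation before fitting (used for the red fox node,
#'   where untransformed covariates hinder convergence).
#'
#' @return An object of class `node_spec`.
#' @export
node_spec <- function(name, family = c("poisson", "binomial"), response,
                      predictors, offset = NULL, random = "trip",
                      denominator = NULL, frame = "captures",
                      factors = character(), z_transform = FALSE) {
  family <- match.arg(family)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.character(predictors), length(predictors) >= 0L)
  if (family == "poisson" && is.null(offset)) {
    stop("poisson node '", name, "' requires an effort offset", call. = FALSE)
  }
  if (family == "binomial") {
    if (is.null(denominator) || denominator <= 0) {
      stop("binomial node '", name, "' requires a positive denominator",
           call. = FALSE)
    }
    offset <- NULL
  }
  # every variable referenced inside an interaction must be a declared
  # main-effect term of the same node
  mains <- predictors[!grepl(":", predictors, fixed = TRUE)]
  for (tm in predictors[grepl(":", predictors, fixed = TRUE)]) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1L]]
    missing_parts <- setdiff(parts, mains)
    if (length(missing_parts)) {
      stop("interaction '", tm, "' references undeclared main effect(s): ",
           paste(missing_parts, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(name = name, family = family, response = response,
         predictors = predictors, offset = offset, random = random,
         denominator = denominator, frame = frame, factors = factors,
         z_transform = isTRUE(z_transform)),
    class = "node_spec"
  )
}

#' @export
print.node_spec <- function(x, ...) {
  link <- if (x$family == "poisson") "log" else "logit"
  rhs <- paste(x$predictors, collapse = " + ")
  off <- if (!is.null(x$offset)) paste0(" + offset(log(", x$offset, "))") else ""
  cat(sprintf("%s(%s) ~ %s + (1 | %s)%s   [%s%s]\n",
              link, x$response, rhs, x$random, off, x$family,
              if (!is.null(x$denominator)) paste0("/", x$denominator) else ""))
  invisible(x)
}

#' Assemble node specifications into a model graph
#'
#' The directed edge set is derived from the specifications: every predictor
#' term of every node contributes exactly one edge (interaction terms count
#' once), pointing from the driver to the node.
#'
#' @param nodes list of [node_spec()] objects.
#' @return An object of class `model_graph` with elements `nodes` (named
#'   list) and `edges` (tibble with columns `source`, `target`,
#'   `endogenous`).
#' @export
model_graph <- function(nodes) {
  stopifnot(is.list(nodes), all(vapply(nodes, inherits, TRUE, "node_spec")))
  names(nodes) <- vapply(nodes, `[[`, "", "name")
  if (anyDuplicated(names(nodes))) {
    stop("duplicate node names in graph", call. = FALSE)
  }
  responses <- vapply(nodes, `[[`, "", "response")
  edges <- dplyr::bind_rows(lapply(nodes, function(nd) {
    if (!length(nd$predictors)) return(NULL)
    tibble::tibble(source = nd$predictors, target = nd$name,
                   # a predictor is an endogenous parent when its column IS
                   # another node's response (cover, seed feeding forward);
                   # effort-standardized rate covariates are exogenous
                   # measurements
                   endogenous = nd$predictors %in% responses)
  }))
  if (is.null(edges) || !nrow(edges)) {
    edges <- tibble::tibble(source = character(), target = character(),
                            endogenous = logical())
  }
  g <- structure(list(nodes = nodes, edges = edges), class = "model_graph")
  cyc <- .endogenous_cycle(g)
  if (length(cyc)) {
    stop("cycle among endogenous nodes: ", paste(cyc, collapse = " -> "),
         call. = FALSE)
  }
  g
}

#' @export
print.model_graph <- function(x, ...) {
  cat(sprintf("model_graph: %d nodes, %d directed effects\n",
              length(x$nodes), count_edges(x)))
  for (nd in x$nodes) print(nd)
  invisible(x)
}

# returns the node names on an endogenous cycle (empty if acyclic)
.endogenous_cycle <- function(graph) {
  resp_to_node <- stats::setNames(names(graph$nodes),
                                  vapply(graph$nodes, `[[`, "", "response"))
  e <- graph$edges[graph$edges$endogenous, , drop = FALSE]
  if (!nrow(e)) return(character())
  parents <- split(unname(resp_to_node[e$source]), e$target)
  state <- stats::setNames(rep(0L, length(graph$nodes)), names(graph$nodes))
  path <- character()
  cycle <- character()
  visit <- function(v) {
    if (length(cycle)) return()
    if (state[[v]] == 1L) {
      cycle <<- c(path[which(path == v)[1L]:length(path)], v)
      return()
    }
    if (state[[v]] == 2L) return()
    state[[v]] <<- 1L
    path <<- c(path, v)
    for (p in parents[[v]]) visit(p)
    path <<- path[-length(path)]
    state[[v]] <<- 2L
  }
  for (v in names(graph$nodes)) visit(v)
  cycle
}

#' Topological order of the endogenous nodes
#'
#' Orders nodes so that every endogenous parent (a node whose response feeds
#' another node as a predictor column) precedes its children; used for the
#' node-by-node scenario propagation (cover, then seed, then rodents).
#'
#' @param graph a [model_graph()].
#' @return Character vector of node names, parents first.
#' @export
topological_order <- function(graph) {
  resp_to_node <- stats::setNames(names(graph$nodes),
                                  vapply(graph$nodes, `[[`, "", "response"))
  e <- graph$edges[graph$edges$endogenous, , drop = FALSE]
  deps <- lapply(graph$nodes, function(nd) {
    unname(resp_to_node[intersect(nd$predictors, names(resp_to_node))])
  })
  out <- character()
  remaining <- names(graph$nodes)
  while (length(remaining)) {
    ready <- remaining[vapply(deps[remaining],
                              function(d) all(d %in% out), TRUE)]
    if (!length(ready)) stop("cycle among endogenous nodes", call. = FALSE)
    out <- c(out, ready)
    remaining <- setdiff(remaining, ready)
  }
  out
}

#' The a priori desert food-web graph
#'
#' Returns the fixed causal network of the study system: nine local models
#' totalling 26 directed effects. Exogenous drivers are eight-month
#' cumulative rainfall (`rain8`, mm), number of rain days in the trapping
#' month (`rain_days`), mean rainfall event size two trips prior
#' (`rain_event_lag2`, mm), years since the last wildfire (`fire_years`),
#' site, and the rodent-prey population phase (boom/decline/bust coded
#' 1/2/3). Endogenous responses are spinifex cover (% of 100), spinifex seed
#' index (0-5), and captures/photo counts of rodents, dasyurids, mulgara,
#' reptiles, dingo, feral cat and red fox. Count predictors enter as
#' effort-standardized rates: captures per 100 trap-nights
#' (`*_rate`), photographs per camera-night for the predators.
#'
#' @return A [model_graph()] with 9 nodes and 26 edges.
#' @export
canonical_graph <- function() {
  model_graph(list(
    node_spec("dasyurids", "poisson", response = "dasyurids",
              predictors = c("site", "rain_event_lag2", "mulgara_rate"),
              offset = "trap_nights", random = "trip", frame = "captures",
              factors = "site"),
    node_spec("cover", "binomial", response = "cover",
              predictors = c("fire_years", "rain8"),
              random = "trip", denominator = 100, frame = "vegetation"),
    node_spec("seed", "binomial", response = "seed",
              predictors = c("cover", "rain8"),
              random = "trip", denominator = 5, frame = "vegetation"),
    node_spec("rodents", "poisson", response = "rodents",
              predictors = c("seed", "cat_rate", "fox_rate", "dingo_rate"),
              offset = "trap_nights", random = "trip",
              frame = "captures_camera_period"),
    node_spec("mulgara", "poisson", response = "mulgara",
              predictors = c("rodent_rate", "cover", "fire_years"),
              offset = "trap_nights", random = "trip", frame = "captures"),
    node_spec("cat", "poisson", response = "cat",
              predictors = c("rodent_rate", "dingo_rate", "phase",
                             "phase:dingo_rate"),
              offset = "camera_nights", random = "month", frame = "camera"),
    node_spec("fox", "poisson", response = "fox",
              predictors = c("rodent_rate", "dingo_rate", "phase",
                             "phase:dingo_rate"),
              offset = "camera_nights", random = "month", frame = "camera",
              z_transform = TRUE),
    node_spec("dingo", "poisson", response = "dingo",
              predictors = "rodent_rate",
              offset = "camera_nights", random = "month", frame = "camera"),
    node_spec("reptiles", "poisson", response = "reptiles",
              predictors = c("fire_years", "cover", "rain_days"),
              offset = "trap_nights", random = "trip", frame = "captures")
  ))
}

#' Count the directed effects of a graph
#'
#' Each predictor term contributes one directed effect; interactions count
#' once. The canonical graph has 26.
#'
#' @param graph a [model_graph()].
#' @return Integer edge count.
#' @export
count_edges <- function(graph) {
  stopifnot(inherits(graph, "model_graph"))
  nrow(graph$edges)
}

#' Validate a graph against a data schema
#'
#' Checks that every referenced column (response, predictors, offset,
#' random factor) exists in the node's analysis table, that model families
#' are coherent (Poisson nodes have an offset, binomial nodes a
#' denominator), and that the endogenous dependency order is resolvable.
#' Violations are returned, not raised, so a caller can report all problems
#' at once.
#'
#' @param graph a [model_graph()].
#' @param schema named list: for each frame name, a character vector of
#'   available columns (a named list of data frames is also accepted).
#' @return Character vector of violations; empty when the graph is valid
#'   against the schema.
#' @export
validate_graph <- function(graph, schema) {
  stopifnot(inherits(graph, "model_graph"))
  cols <- lapply(schema, function(s) if (is.data.frame(s)) names(s) else s)
  out <- character()
  for (nd in graph$nodes) {
    have <- cols[[nd$frame]]
    if (is.null(have)) {
      out <- c(out, sprintf("node '%s': no table '%s' in schema",
                            nd$name, nd$frame))
      next
    }
    vars <- unique(unlist(strsplit(nd$predictors, ":", fixed = TRUE)))
    need <- c(nd$response, vars, nd$offset, nd$random)
    for (m in setdiff(need, have)) {
      out <- c(out, sprintf("node '%s': missing column '%s' in table '%s'",
                            nd$name, m, nd$frame))
    }
    if (nd$family == "poisson" && is.null(nd$offset)) {
      out <- c(out, sprintf("node '%s': poisson node without offset", nd$name))
    }
    if (nd$family == "binomial" &&
        (is.null(nd$denominator) || nd$denominator <= 0)) {
      out <- c(out, sprintf("node '%s': binomial node without denominator",
                            nd$name))
    }
  }
  cyc <- .endogenous_cycle(graph)
  if (length(cyc)) {
    out <- c(out, paste0("cycle among endogenous nodes: ",
                         paste(cyc, collapse = " -> ")))
  }
  out
}

#' Serialize a model graph to a plain-text config
#'
#' One block per node, `key: value` lines, stable ordering; the exact
#' inverse of [read_graph_config()] so round-trips are bit-identical.
#'
#' @param graph a [model_graph()].
#' @param path file to write; if `NULL`, the lines are returned invisibly.
#' @return Character vector of config lines, invisibly.
#' @export
write_graph_config <- function(graph, path = NULL) {
  fmt <- function(x) {
    if (is.null(x) || !length(x)) "." else paste(as.character(x), collapse = ",")
  }
  lines <- unlist(lapply(graph$nodes, function(nd) {
    c(sprintf("[node %s]", nd$name),
      sprintf("family: %s", nd$family),
      sprintf("response: %s", nd$response),
      sprintf("predictors: %s", fmt(nd$predictors)),
      sprintf("offset: %s", fmt(nd$offset)),
      sprintf("random: %s", nd$random),
      sprintf("denominator: %s", fmt(nd$denominator)),
      sprintf("frame: %s", nd$frame),
      sprintf("factors: %s", fmt(nd$factors)),
      sprintf("z_transform: %s", if (nd$z_transform) "yes" else "no"),
      "")
  }))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read a model graph from a plain-text config
#'
#' @param path file written by [write_graph_config()] (or a character vector
#'   of config lines).
#' @return A [model_graph()].
#' @export
read_graph_config <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- lines[nzchar(lines)]
  starts <- grep("^\\[node ", lines)
  ends <- c(starts[-1L] - 1L, length(lines))
  unfmt <- function(x) if (identical(x, ".")) NULL else strsplit(x, ",", fixed = TRUE)[[1L]]
  nodes <- lapply(seq_along(starts), function(i) {
    blk <- lines[starts[i]:ends[i]]
    name <- sub("^\\[node (.*)\\]$", "\\1", blk[1L])
    kv <- blk[-1L]
    keys <- sub(":.*$", "", kv)
    vals <- sub("^[^:]*: ?", "", kv)
    get <- function(k) unname(vals[match(k, keys)])
    denom <- unfmt(get("denominator"))
    node_spec(name, family = get("family"), response = get("response"),
              predictors = unfmt(get("predictors")) %||% character(),
              offset = unfmt(get("offset")), random = get("random"),
              denominator = if (!is.null(denom)) as.numeric(denom),
              frame = get("frame"),
              factors = unfmt(get("factors")) %||% character(),
              z_transform = identical(get("z_transform"), "yes"))
  })
  model_graph(nodes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
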
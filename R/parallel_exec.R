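#' Backend-agnostic map/reduce task plans
#'
#' A `task_plan` describes a computation over a source collection as a chain
#' of lazily composed transforms (map, filter) ending in an eager action
#' (collect, or reduce with an associative and commutative combiner). Plans
#' only record the computation; [pexec_run()] evaluates them. The contract is
#' that the result is identical to sequential left-to-right evaluation for
#' every partition count and backend, which is what lets the center-star
#' gap-profile reduce and the per-cluster tree builds run on any number of
#' workers without changing output.
#'
#' @param source a list or vector of elements.
#' @param partitions number of contiguous partitions the source is split into.
#' @param backend `"sequential"` evaluates partitions in a simple loop;
#'   `"workers"` evaluates them in parallel forks via [parallel::mclapply()].
#' @return an object of class `task_plan`.
#' @export
task_plan <- function(source, partitions = 1L,
                      backend = c("sequential", "workers")) {
  backend <- match.arg(backend)
  partitions <- max(1L, as.integer(partitions))
  structure(list(source = as.list(source), transforms = list(), action = NULL,
                 partitions = partitions, backend = backend),
            class = "task_plan")
}

#' @rdname task_plan
#' @param plan a `task_plan`.
#' @param f pure function applied to each element.
#' @export
plan_map <- function(plan, f) {
  stopifnot(inherits(plan, "task_plan"), is.function(f))
  plan$transforms <- c(plan$transforms, list(list(kind = "map", f = f)))
  plan
}

#' @rdname task_plan
#' @param p pure predicate; elements where it returns `FALSE` are dropped.
#' @export
plan_filter <- function(plan, p) {
  stopifnot(inherits(plan, "task_plan"), is.function(p))
  plan$transforms <- c(plan$transforms, list(list(kind = "filter", f = p)))
  plan
}

#' @rdname task_plan
#' @export
plan_collect <- function(plan) {
  stopifnot(inherits(plan, "task_plan"))
  plan$action <- list(kind = "collect")
  plan
}

#' @rdname task_plan
#' @param combiner associative and commutative binary function.
#' @param identity identity element of `combiner`.
#' @export
plan_reduce <- function(plan, combiner, identity) {
  stopifnot(inherits(plan, "task_plan"), is.function(combiner))
  plan$action <- list(kind = "reduce", combiner = combiner,
                      identity = identity)
  plan
}

# apply the transform chain to one partition (a list of elements)
apply_transforms <- function(elems, transforms) {
  for (tr in transforms) {
    if (tr$kind == "map") {
      elems <- lapply(elems, tr$f)
    } else {
      keep <- vapply(elems, function(e) isTRUE(tr$f(e)), logical(1))
      elems <- elems[keep]
    }
  }
  elems
}

# sample up to three transformed elements and check the combiner's
# associativity and commutativity on them
check_combiner <- function(elems, combiner) {
  if (length(elems) < 2) return(invisible(TRUE))
  idx <- unique(c(1L, (length(elems) + 1L) %/% 2L, length(elems)))
  s <- elems[idx]
  a <- s[[1]]; b <- s[[min(2, length(s))]]; c <- s[[length(s)]]
  if (!isTRUE(all.equal(combiner(a, b), combiner(b, a))))
    stop("configuration error: reduce combiner is not commutative")
  if (!isTRUE(all.equal(combiner(combiner(a, b), c),
                        combiner(a, combiner(b, c)))))
    stop("configuration error: reduce combiner is not associative")
  invisible(TRUE)
}

#' Evaluate a task plan
#'
#' Splits the source into the plan's partitions, evaluates each partition
#' (sequentially or in worker forks), and combines partition results in a
#' fixed order, so the result never depends on partitioning or backend.
#' Reduce combiners are self-tested for associativity and commutativity on
#' sampled elements before use.
#'
#' @param plan a [task_plan] with an action attached.
#' @return the collected list, or the reduced value.
#' @export
pexec_run <- function(plan) {
  stopifnot(inherits(plan, "task_plan"))
  if (is.null(plan$action)) stop("plan has no terminal action")
  n <- length(plan$source)
  nn <- min(plan$partitions, max(1L, n))
  bounds <- if (n == 0) list(integer(0)) else
    unname(split(seq_len(n),
                 rep(seq_len(nn), each = ceiling(n / nn))[seq_len(n)]))
  eval_part <- function(idx) apply_transforms(plan$source[idx], plan$transforms)
  parts <- if (plan$backend == "workers" && length(bounds) > 1) {
    parallel::mclapply(bounds, eval_part,
                       mc.cores = min(length(bounds),
                                      max(2L, parallel::detectCores())))
  } else {
    lapply(bounds, eval_part)
  }
  if (plan$action$kind == "collect") {
    out <- do.call(c, c(parts, list(list())))
    names(out) <- NULL
    return(out)
  }
  comb <- plan$action$combiner
  all_elems <- do.call(c, c(parts, list(list())))
  check_combiner(all_elems, comb)
  part_vals <- lapply(parts, function(p) Reduce(comb, p, plan$action$identity))
  Reduce(comb, part_vals, plan$action$identity)
}

#' Broadcast a read-only value to all tasks
#'
#' Wraps a value in a locked binding so every task observes the identical
#' object and mutation attempts fail.
#'
#' @param value any immutable R value.
#' @return an object of class `broadcast`; read it with [bc_value()].
#' @export
broadcast <- function(value) {
  env <- new.env(parent = emptyenv())
  assign("value", value, envir = env)
  lockEnvironment(env, bindings = TRUE)
  structure(list(env = env), class = "broadcast")
}

#' @rdname broadcast
#' @param bc a `broadcast` handle.
#' @export
bc_value <- function(bc) {
  stopifnot(inherits(bc, "broadcast"))
  get("value", envir = bc$env)
}
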
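# Synthetic stimulus generator: the object/transformation world the model
# learns from, and the A:B::C:D geometric analogy batteries it is tested on.

#' The five geometric transformations
#'
#' Four unary transformations (adding an element, changing size, halving,
#' doubling), each defined by two semantic units, and one binary relational
#' transformation (changing containment) whose two roles, outside and
#' inside, are each defined by two semantic units.  The defining semantics
#' occupy pool ids 0--11 and are disjoint from each other and from all
#' idiosyncratic object features (which are drawn from ids 12 and above).
#'
#' @return A data frame with one row per transformation: `name`, `arity`.
#' @export
transformations <- function() {
  data.frame(
    name = c("add_element", "change_size", "halving", "doubling",
             "change_containment"),
    arity = c(1L, 1L, 1L, 1L, 2L),
    stringsAsFactors = FALSE
  )
}

#' Defining semantics of every transformation role
#'
#' @return Named list mapping each role (the four unary transformations
#'   plus `outside` and `inside`) to its two defining semantic ids.
#' @export
role_semantics <- function() {
  list(
    add_element = c(0L, 1L),
    change_size = c(2L, 3L),
    halving     = c(4L, 5L),
    doubling    = c(6L, 7L),
    outside     = c(8L, 9L),
    inside      = c(10L, 11L)
  )
}

# first pool id usable as an idiosyncratic object feature
feature_floor <- function() 12L

#' Generate the object world used for relational learning
#'
#' Each object is attached (weight 1) to the defining semantics of between
#' two and four transformations chosen at random; when the binary
#' containment transformation is chosen, the object receives the semantics
#' of exactly one of its roles, chosen at random.  Every object also
#' carries `n_features` idiosyncratic feature semantics drawn from the
#' non-defining part of the pool.
#'
#' @param n_objects number of objects.
#' @param pool_size size of the semantic pool.
#' @param n_features idiosyncratic features per object.
#' @return An object of class `dora_world`: a list with `objects` (each a
#'   list with the weight vector `w`, the chosen `transforms` and `roles`)
#'   and the generator settings.
#' @examples
#' set.seed(42)
#' w <- generate_world(n_objects = 10, pool_size = 200)
#' length(w$objects)
#' @export
generate_world <- function(n_objects = 100L, pool_size = 1000L,
                           n_features = 4L) {
  roles <- role_semantics()
  tf <- transformations()
  if (pool_size < feature_floor() + n_features) {
    stop("pool too small for the transformation semantics plus features")
  }
  objects <- lapply(seq_len(n_objects), function(i) {
    n_t <- sample(2:4, 1L)
    chosen <- tf$name[sample.int(nrow(tf), n_t)]
    obj_roles <- unlist(lapply(chosen, function(nm) {
      if (nm == "change_containment") sample(c("outside", "inside"), 1L)
      else nm
    }))
    sems <- unlist(roles[obj_roles], use.names = FALSE)
    feats <- sample(seq.int(feature_floor(), pool_size - 1L), n_features)
    w <- rep(1, length(sems) + n_features)
    names(w) <- as.character(c(sems, feats))
    list(w = w, transforms = chosen, roles = obj_roles, features = feats)
  })
  structure(list(objects = objects, n_objects = as.integer(n_objects),
                 pool_size = as.integer(pool_size),
                 n_features = as.integer(n_features)),
            class = "dora_world")
}

#' @export
print.dora_world <- function(x, ...) {
  cat("Object world:", x$n_objects, "objects over a pool of", x$pool_size,
      "semantics\n")
  nt <- vapply(x$objects, function(o) length(o$transforms), integer(1))
  cat("  transformations per object:", paste(range(nt), collapse = "-"), "\n")
  invisible(x)
}

#' Structural difficulty of a geometric analogy item
#'
#' `0.5 * elements + 1 * transformations`.
#'
#' @param elements number of elements (object POs) in the A term.
#' @param transformations number of transformations relating A to B.
#' @return Numeric difficulty score (vectorised).
#' @examples
#' difficulty_score(2, 1)  # 2
#' difficulty_score(4, 3)  # 5
#' @export
difficulty_score <- function(elements, transformations) {
  if (any(elements < 0) || any(transformations < 0)) {
    stop("elements and transformations must be non-negative")
  }
  0.5 * elements + transformations
}

# Largest-remainder apportionment of n into shares, with ties and
# remainders resolved in the order the shares are listed.
apportion <- function(n, shares) {
  raw <- n * shares
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- raw - base
    ord <- order(-frac, seq_along(shares))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# instance-type recipes per difficulty class, in documented order
hard_submixes <- list(
  c("binary", "binary", "unary"),
  c("binary", "unary", "unary"),
  c("unary", "unary", "unary")
)
medium_submixes <- list(
  c("binary", "binary"),
  c("unary", "unary"),
  c("binary", "unary")
)

make_problem <- function(kinds, difficulty_class, pool_size, n_features = 4L) {
  unary_names <- c("add_element", "change_size", "halving", "doubling")
  n_un <- sum(kinds == "unary")
  un_types <- sample(unary_names, n_un)
  instances <- list()
  obj_counter <- 0L
  ui <- 0L
  for (k in kinds) {
    if (k == "unary") {
      ui <- ui + 1L
      instances[[length(instances) + 1L]] <-
        list(type = un_types[ui], arity = 1L,
             objects = obj_counter + 1L)
      obj_counter <- obj_counter + 1L
    } else {
      instances[[length(instances) + 1L]] <-
        list(type = "change_containment", arity = 2L,
             objects = obj_counter + c(1L, 2L))
      obj_counter <- obj_counter + 2L
    }
  }
  n_obj <- obj_counter
  # idiosyncratic features: disjoint within a problem, A and C disjoint
  feats <- sample(seq.int(feature_floor(), pool_size - 1L),
                  2L * n_obj * n_features)
  fmat <- matrix(feats, nrow = 2L * n_obj, byrow = TRUE)
  a_features <- lapply(seq_len(n_obj), function(i) fmat[i, ])
  c_features <- lapply(seq_len(n_obj), function(i) fmat[n_obj + i, ])
  # correct D as role structure over C-term object indices: for unary
  # instances the transformation applies to the object's image; for the
  # containment change the two roles are exchanged between the objects.
  correct_d <- lapply(instances, function(inst) {
    if (inst$arity == 1L) {
      list(type = inst$type,
           pairs = list(list(role = inst$type, obj = inst$objects)))
    } else {
      list(type = inst$type,
           pairs = list(list(role = "outside", obj = inst$objects[2]),
                        list(role = "inside", obj = inst$objects[1])))
    }
  })
  structure(list(
    instances = instances,
    n_transformations = length(instances),
    elements = n_obj,
    difficulty_class = difficulty_class,
    difficulty = difficulty_score(n_obj, length(instances)),
    a_features = a_features,
    c_features = c_features,
    correct_d = correct_d
  ), class = "dora_problem")
}

#' Generate a battery of A:B::C:D analogy problems
#'
#' The difficulty mix is 30% hard (three transformations), 35% medium
#' (two) and 35% easy (one), apportioned at finite `n` by largest
#' remainder in the order hard, medium, easy; for `n = 20` this gives 6
#' hard, 7 medium and 7 easy items.  Within each class the stated
#' unary/binary sub-mixes are apportioned the same way in the order the
#' recipes are listed (hard: 2 binary + 1 unary, 1 binary + 2 unary, 3
#' unary; medium: 2 binary, 2 unary, 1 binary + 1 unary; easy: binary,
#' unary, with the remainder to unary).  The C and D terms instantiate the
#' same transformations as A and B over different objects, and the correct
#' D is stored as a role structure.
#'
#' @param n number of problems.
#' @param pool_size semantic pool size (shared with the learning world).
#' @return List of `dora_problem` objects with attribute `class_counts`.
#' @examples
#' set.seed(7)
#' b <- generate_battery(20)
#' table(vapply(b, function(p) p$difficulty_class, character(1)))
#' @export
generate_battery <- function(n = 20L, pool_size = 1000L) {
  stopifnot(n >= 1)
  counts <- apportion(n, c(hard = 0.30, medium = 0.35, easy = 0.35))
  hard_counts <- apportion(counts[1], rep(1 / 3, 3))
  med_counts <- apportion(counts[2], rep(1 / 3, 3))
  n_easy_binary <- counts[3] %/% 2L   # remainder goes to unary
  problems <- list()
  for (i in seq_len(3)) {
    for (j in seq_len(hard_counts[i])) {
      problems[[length(problems) + 1L]] <-
        make_problem(hard_submixes[[i]], "hard", pool_size)
    }
  }
  for (i in seq_len(3)) {
    for (j in seq_len(med_counts[i])) {
      problems[[length(problems) + 1L]] <-
        make_problem(medium_submixes[[i]], "medium", pool_size)
    }
  }
  for (j in seq_len(counts[3])) {
    kind <- if (j <= n_easy_binary) "binary" else "unary"
    problems[[length(problems) + 1L]] <-
      make_problem(kind, "easy", pool_size)
  }
  attr(problems, "class_counts") <- counts
  problems
}
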
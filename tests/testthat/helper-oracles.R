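# Independent oracles used across the suite.  These deliberately avoid
# the package's serialization/hashing code paths: deep equality is
# decided by direct recursive structural comparison, partitions by
# all-pairs comparison.

# Recursive deep-equality oracle for metadata trees.  Mappings are
# compared on sorted key sets (insertion order irrelevant); leaves are
# equal when they are the same kind (string vs non-string) and the same
# value; numeric leaves compare by value so the integer 300 equals the
# double 300.
deep_equal_oracle <- function(a, b) {
  a_map <- is.list(a)
  b_map <- is.list(b)
  if (a_map != b_map) return(FALSE)
  if (a_map) {
    ka <- sort(names(a) %||0% character())
    kb <- sort(names(b) %||0% character())
    if (!identical(ka, kb)) return(FALSE)
    for (k in ka) {
      if (!deep_equal_oracle(a[[k]], b[[k]])) return(FALSE)
    }
    return(TRUE)
  }
  if (is.null(a) || is.null(b)) return(is.null(a) && is.null(b))
  if (is.character(a) != is.character(b)) return(FALSE)
  if (is.character(a)) {
    return(identical(stringi::stri_trans_nfc(a), stringi::stri_trans_nfc(b)))
  }
  if (is.logical(a) != is.logical(b)) return(FALSE)
  if (is.logical(a)) return(identical(a, b))
  is.numeric(a) && is.numeric(b) && as.numeric(a) == as.numeric(b)
}

`%||0%` <- function(x, y) if (is.null(x)) y else x

# Brute-force O(N^2) partition oracle: groups files by pairwise deep
# equality of their trees.  Returns a list of index vectors.
partition_oracle <- function(trees) {
  n <- length(trees)
  assigned <- rep(NA_integer_, n)
  g <- 0L
  for (i in seq_len(n)) {
    if (!is.na(assigned[i])) next
    g <- g + 1L
    assigned[i] <- g
    if (i < n) {
      for (j in seq((i + 1L), n)) {
        if (is.na(assigned[j]) && deep_equal_oracle(trees[[i]], trees[[j]])) {
          assigned[j] <- g
        }
      }
    }
  }
  split(seq_len(n), assigned)
}

# Path-wise copy oracle: rebuild a tree keeping only leaf paths not in
# `exclude` (exact escaped-path match).  Used to check exclusion-list
# stripping against an independent construction.
path_copy_oracle <- function(tree, exclude = character()) {
  paths <- tree_leaf_paths_oracle(tree)
  out <- list()
  for (p in paths) {
    if (p$joined %in% exclude) next
    if (any(vapply(exclude, function(e) {
      identical(p$joined, e) || startsWith(p$joined, paste0(e, "/"))
    }, logical(1)))) next
    out <- assign_path_oracle(out, p$keys, p$value)
  }
  out
}

tree_leaf_paths_oracle <- function(tree, prefix = character()) {
  if (!is.list(tree)) {
    esc <- gsub("/", "\\\\/", gsub("\\\\", "\\\\\\\\", prefix))
    return(list(list(keys = prefix, joined = paste(esc, collapse = "/"),
                     value = tree)))
  }
  if (length(tree) == 0L && length(prefix) > 0L) return(list())
  unlist(lapply(names(tree), function(k) {
    tree_leaf_paths_oracle(tree[[k]], c(prefix, k))
  }), recursive = FALSE)
}

assign_path_oracle <- function(tree, keys, value) {
  if (length(keys) == 1L) {
    tree[keys] <- list(value)
    return(tree)
  }
  sub <- if (keys[1] %in% names(tree)) tree[[keys[1]]] else list()
  tree[[keys[1]]] <- assign_path_oracle(sub, keys[-1], value)
  tree
}

# Seeded random metadata tree, used by property tests.  Keys draw from a
# pool that includes separator and non-ASCII characters.
random_tree <- function(depth = 3L, max_children = 4L) {
  key_pool <- c("alpha", "beta", "Sigma", "m/z", "tune file", "résol",
                "AGC", "NCE", "pµl", "scan")
  n <- sample.int(max_children, 1L)
  keys <- sample(paste0(key_pool, sample.int(99, length(key_pool))), n)
  out <- list()
  for (k in keys) {
    roll <- stats::runif(1)
    out[[k]] <- if (depth > 0L && roll < 0.35) {
      random_tree(depth - 1L, max_children)
    } else if (roll < 0.55) {
      sample(c("positive", "negative", "Full MS", "300 to 1750"), 1L)
    } else if (roll < 0.75) {
      round(stats::runif(1, 0, 5000), 3)
    } else if (roll < 0.85) {
      sample.int(100000L, 1L)
    } else if (roll < 0.95) {
      stats::runif(1) < 0.5
    } else {
      NULL
    }
  }
  out
}

# Mutate one random leaf of a tree to a fresh value; returns the mutated
# tree (guaranteed different from the input at that leaf).
perturb_leaf <- function(tree) {
  paths <- tree_leaf_paths_oracle(tree)
  if (length(paths) == 0L) return(list(new_leaf = "x"))
  p <- paths[[sample.int(length(paths), 1L)]]
  new_val <- paste0("perturbed-", sample.int(1e6, 1L))
  assign_path_oracle(tree, p$keys, new_val)
}

# Recursively shuffle sibling order (content-preserving permutation).
shuffle_tree <- function(tree) {
  if (!is.list(tree) || length(tree) == 0L) return(tree)
  tree <- tree[sample(seq_along(tree))]
  for (k in names(tree)) tree[[k]] <- shuffle_tree(tree[[k]])
  tree
}

# Independent recursive diff oracle: paths present in either tree whose
# subtree/leaf values disagree under deep equality.
oracle_diff_paths <- function(a, b, prefix = character()) {
  if (!is.list(a) || !is.list(b)) {
    esc <- gsub("/", "\\\\/", gsub("\\\\", "\\\\\\\\", prefix))
    if (deep_equal_oracle(a, b)) return(character())
    return(paste(esc, collapse = "/"))
  }
  keys <- union(names(a), names(b))
  unlist(lapply(keys, function(k) {
    if (!k %in% names(a) || !k %in% names(b)) {
      esc <- gsub("/", "\\\\/", gsub("\\\\", "\\\\\\\\", c(prefix, k)))
      return(paste(esc, collapse = "/"))
    }
    oracle_diff_paths(a[[k]], b[[k]], c(prefix, k))
  }), use.names = FALSE)
}

# Tiny fixture used by several files: a two-instrument record.
make_fixture_meta <- function(file_name = "a.json",
                              date = "2019-01-07T09:00:00Z",
                              nce = 27) {
  file_metadata(
    file_name = file_name, acquired_date = date,
    sample_info = list("Sample id" = "S-1", "Vial" = "A1"),
    instruments = list(
      instrument_metadata(
        model = "Q Exactive - Orbitrap_MS", module_type = "MS",
        parameters = list(Tune = list("Spray voltage (kV)" = 2.1),
                          Method = list("NCE" = nce))),
      instrument_metadata(
        model = "Thermo EASY-nLC", module_type = "LC",
        method_text = "Gradient:\n  0 / 5 / 300 / 5\n  5 / 55 / 300 / 38\n  60 / 5 / 300 / 95\nSample pickup: 2 µl",
        parameters = list(Properties = list("Mobile phase A" = "0.1% FA")))
    ))
}
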
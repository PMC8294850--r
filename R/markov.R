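#' @import data.table
NULL

.node_labels <- function(maze, nodes, pooling) {
  if (pooling == "none") return(as.character(nodes))
  # pool T-junctions by (level, left/right type); the root has no parent
  # turn and keeps its own label
  paste0(maze$level[nodes + 1L], maze$lr_type[nodes + 1L])
}

#' Junction decision table of a trajectory
#'
#' One row per T-junction decision during explore mode: the action taken
#' (`"L"` = in left, `"R"` = in right, `"O"` = out), the incoming four-code
#' action (for the biased-walk baseline) and the history keys at depths
#' 1..`kmax` (comma-joined node labels ending at the current junction).
#' Histories never span clip boundaries. End-node decisions are excluded
#' because they are fully predictable.
#'
#' @param seq A `node_sequence` or `sim_session`.
#' @param maze A `maze_graph`.
#' @param kmax Deepest history tracked (default 6).
#' @param pooling `"none"` or `"lr_level"` (pool node labels by level and
#'   left/right type).
#' @param mode_filter Restrict to explore mode (default TRUE; set FALSE for
#'   bare agent walks without modes).
#' @param ... Passed to [segment_modes()].
#' @return A data.frame: `node`, `action`, `a0`, `key1`..`key<kmax>`.
#' @export
markov_decisions <- function(seq, maze, kmax = 6L,
                             pooling = c("none", "lr_level"),
                             mode_filter = TRUE, ...) {
  pooling <- match.arg(pooling)
  if (inherits(seq, "sim_session")) seq <- seq$seq
  runs <- if (mode_filter) {
    lapply(explore_clips(seq, maze, ...), function(idx) seq$node[idx])
  } else {
    b <- segment_bouts(seq)
    Map(function(s, e) seq$node[s:e], b$start, b$end)
  }
  out <- vector("list", length(runs))
  for (ci in seq_along(runs)) {
    v <- runs[[ci]]
    if (length(v) < 2L) next
    lab <- .node_labels(maze, v, pooling)
    acts4 <- .step_actions(v)
    n <- length(v)
    # action at position i is the step v[i] -> v[i+1]; in-steps carry the
    # geometric branch label of the link taken
    nxt <- c(v[-1L], NA_integer_)
    dn <- !is.na(nxt) & nxt > v
    g <- rep(NA_integer_, n)
    g[dn] <- .edge_gsign(v[dn], nxt[dn])
    act3 <- ifelse(dn, ifelse(g < 0L, "L", "R"), "O")[-n]
    keys <- matrix(NA_character_, n, kmax)
    keys[, 1L] <- lab
    if (kmax > 1L) for (k in 2:kmax) {
      idx <- k:n
      keys[idx, k] <- paste(keys[idx - 1L, k - 1L], lab[idx], sep = ",")
    }
    pos <- which(maze$node_kind[v[-n] + 1L] == "junction")
    if (!length(pos)) next
    df <- data.frame(node = v[pos], action = act3[pos],
                     a0 = c(NA_integer_, acts4)[pos],
                     stringsAsFactors = FALSE)
    kd <- as.data.frame(keys[pos, , drop = FALSE])
    names(kd) <- paste0("key", seq_len(kmax))
    out[[ci]] <- cbind(df, kd)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    stop("no junction decisions in the trajectory", call. = FALSE)
  do.call(rbind, out)
}

.count_table <- function(keys, actions) {
  dt <- data.table::data.table(hkey = keys, action = actions)
  dt <- dt[!is.na(hkey)]
  cnt <- dt[, list(N = .N), by = c("hkey", "action")]
  wide <- data.table::dcast(cnt, hkey ~ action, value.var = "N", fill = 0L)
  for (a in c("L", "R", "O"))
    if (!a %in% names(wide)) wide[[a]] <- 0L
  data.table::setkey(wide, hkey)
  wide[, c("hkey", "L", "R", "O"), with = FALSE]
}

#' Fit a Markov model of junction decisions
#'
#' Tallies history-action counts n(h, a) on a training decision table and
#' predicts with Laplace smoothing: p(a|h) = (n(h,a)+1)/(sum n + 3), so an
#' unseen history predicts (1/3, 1/3, 1/3). The fixed-depth model uses
#' histories of exactly `depth` nodes. The variable-depth model keeps the
#' history tree pruned so that every surviving branch has more than `m`
#' training counts (suffix-closed retention) and predicts from the deepest
#' retained suffix of the current history.
#'
#' @param decisions A [markov_decisions()] table (the training split).
#' @param depth Fixed history depth k, or `NULL` for variable depth.
#' @param kmax Maximum depth of the variable model (default 6).
#' @param m Count threshold of the variable model (default 10).
#' @return Object of class `markov_model`.
#' @export
fit_markov <- function(decisions, depth = 1L, kmax = 6L, m = 10L) {
  if (!nrow(decisions)) stop("empty training split", call. = FALSE)
  avail <- sum(grepl("^key[0-9]+$", names(decisions)))
  if (is.null(depth)) {
    kmax <- min(kmax, avail)
    tabs <- vector("list", kmax)
    retained <- NULL
    for (k in seq_len(kmax)) {
      tab <- .count_table(decisions[[paste0("key", k)]], decisions$action)
      tab[, total := L + R + O]
      if (k == 1L) {
        tab <- tab[total > 0L]
      } else {
        # suffix of a depth-k key = drop its oldest label
        suffix <- sub("^[^,]*,", "", tab$hkey)
        tab <- tab[total > m & suffix %in% retained]
      }
      retained <- tab$hkey
      data.table::setkey(tab, hkey)
      tabs[[k]] <- tab
    }
    model <- list(kind = "variable", kmax = kmax, m = m, tables = tabs)
  } else {
    if (depth > avail) stop("decision table lacks depth ", depth, call. = FALSE)
    tab <- .count_table(decisions[[paste0("key", depth)]], decisions$action)
    data.table::setkey(tab, hkey)
    model <- list(kind = "fixed", k = as.integer(depth), tables = list(tab))
  }
  class(model) <- "markov_model"
  model
}

#' @export
print.markov_model <- function(x, ...) {
  if (x$kind == "fixed")
    cat(sprintf("markov_model: fixed depth k=%d, %d histories\n",
                x$k, nrow(x$tables[[1L]])))
  else
    cat(sprintf("markov_model: variable depth (kmax=%d, m=%d), %d retained histories\n",
                x$kmax, x$m,
                sum(vapply(x$tables, nrow, integer(1)))))
  invisible(x)
}

#' Predict action probabilities for a decision table
#'
#' @param object A `markov_model`.
#' @param decisions A [markov_decisions()] table.
#' @param ... Unused.
#' @return List with `prob` (n x 3 matrix, columns L, R, O) and `depth`
#'   (history depth used per row; 0 means no usable history, uniform
#'   prediction).
#' @export
predict.markov_model <- function(object, decisions, ...) {
  n <- nrow(decisions)
  counts <- matrix(0, n, 3, dimnames = list(NULL, c("L", "R", "O")))
  depth_used <- integer(n)
  depths <- if (object$kind == "fixed") object$k else seq_len(object$kmax)
  for (j in seq_along(depths)) {
    k <- depths[j]
    tab <- object$tables[[j]]
    idx <- match(decisions[[paste0("key", k)]], tab$hkey)
    hit <- !is.na(idx)
    if (any(hit)) {
      counts[hit, ] <- as.matrix(tab[idx[hit], c("L", "R", "O"), with = FALSE])
      depth_used[hit] <- k
    }
    # variable model: deeper retained suffixes overwrite shallower ones
  }
  prob <- (counts + 1) / (rowSums(counts) + 3)
  list(prob = prob, depth = depth_used)
}

#' Cross-entropy of model predictions on a decision table
#'
#' Mean -log2 p(a_t | h_t) over the decisions, in bits per action; the
#' uniform baseline is log2(3) = 1.585 bits.
#'
#' @param model A `markov_model` (or `"uniform"`, or a `bias_set` for the
#'   biased-random-walk baseline).
#' @param decisions A [markov_decisions()] table (the test split).
#' @return List of class `cross_entropy_report`: `H` (bits/action), `n`,
#'   `mean_history_length`.
#' @export
cross_entropy <- function(model, decisions) {
  if (identical(model, "uniform")) {
    out <- list(H = log2(3), n = nrow(decisions), mean_history_length = 0)
    class(out) <- "cross_entropy_report"
    return(out)
  }
  if (inherits(model, "bias_set")) {
    p <- .bias_action_prob(model, decisions)
    keep <- !is.na(p)
    out <- list(H = mean(-log2(p[keep])), n = sum(keep),
                mean_history_length = 1)
    class(out) <- "cross_entropy_report"
    return(out)
  }
  pr <- predict.markov_model(model, decisions)
  # fixed-depth models score only decisions with a full-depth history
  keep <- if (model$kind == "fixed") {
    !is.na(decisions[[paste0("key", model$k)]])
  } else rep(TRUE, nrow(decisions))
  p <- pr$prob[cbind(seq_len(nrow(decisions)),
                     match(decisions$action, c("L", "R", "O")))]
  out <- list(H = mean(-log2(p[keep])), n = sum(keep),
              mean_history_length = mean(pmax(pr$depth[keep], 1)))
  class(out) <- "cross_entropy_report"
  out
}

#' @export
print.cross_entropy_report <- function(x, ...) {
  cat(sprintf("cross-entropy: %.3f bits/action over %d decisions (mean history %.2f)\n",
              x$H, x$n, x$mean_history_length))
  invisible(x)
}

# probability the four-bias policy assigns to the observed 3-action, given
# the incoming 4-code action a0; NA where a0 is unknown
.bias_action_prob <- function(b, decisions) {
  a0 <- decisions$a0; act <- decisions$action; node <- decisions$node
  p <- rep(NA_real_, nrow(decisions))
  from_stem <- !is.na(a0) & a0 %in% c(0L, 1L)
  from_bar <- !is.na(a0) & a0 %in% c(2L, 3L)
  # stem arrival: out = reversal; in-actions split by alternation
  alt_act <- ifelse(a0 == 0L, "R", "L")      # alternating turn
  p[from_stem & act == "O"] <- 1 - b$PSF
  p[from_stem & act == alt_act] <- b$PSF * b$PSA
  p[from_stem & act != "O" & act != alt_act] <- b$PSF * (1 - b$PSA)
  # bar arrival: reversal re-enters the child just left
  back_act <- ifelse(a0 == 2L, "L", "R")
  p[from_bar & act == back_act] <- 1 - b$PBF
  p[from_bar & act == "O"] <- b$PBF * b$PBS
  p[from_bar & act != "O" & act != back_act] <- b$PBF * (1 - b$PBS)
  p
}

#' Cross-validated cross-entropy of a decision model
#'
#' Splits the decisions into five folds of interleaved fixed-length chunks
#' (so each fold samples the whole session evenly), trains on 80% and tests
#' on 20%, and averages the cross-entropy over the five splits.
#'
#' @param decisions A [markov_decisions()] table.
#' @param depth,kmax,m Model specification passed to [fit_markov()]; use
#'   `model = "uniform"` or a `bias_set` for the baselines.
#' @param model Optional baseline instead of a Markov fit.
#' @param folds Number of folds (default 5).
#' @param chunk Chunk length in decisions (default 500).
#' @return List: `H` (mean over folds), `per_fold`, `mean_history_length`.
#' @export
markov_cv <- function(decisions, depth = 1L, kmax = 6L, m = 10L,
                      model = NULL, folds = 5L, chunk = 500L) {
  n <- nrow(decisions)
  if (n < folds) stop("sequence too short for cross-validation", call. = FALSE)
  fold_id <- (((seq_len(n) - 1L) %/% chunk) %% folds) + 1L
  if (length(unique(fold_id)) < folds)
    fold_id <- ((seq_len(n) - 1L) %% folds) + 1L
  H <- mh <- numeric(folds)
  for (f in seq_len(folds)) {
    train <- decisions[fold_id != f, , drop = FALSE]
    test <- decisions[fold_id == f, , drop = FALSE]
    fitted <- if (is.null(model)) {
      fit_markov(train, depth = depth, kmax = kmax, m = m)
    } else if (inherits(model, "bias_set") || identical(model, "uniform")) {
      model
    } else model
    rep <- cross_entropy(fitted, test)
    H[f] <- rep$H; mh[f] <- rep$mean_history_length
  }
  list(H = mean(H), per_fold = H, mean_history_length = mean(mh))
}

#' Compare junction-decision models by held-out cross-entropy
#'
#' Evaluates fixed-depth Markov chains over a depth grid, variable-depth
#' chains over a count-threshold grid, the four-bias baseline and the
#' uniform baseline, all under the same 5-fold interleaved cross-validation.
#'
#' @param seq A `node_sequence` or `sim_session`.
#' @param maze A `maze_graph`.
#' @param ks Fixed depths to evaluate (default 1:4).
#' @param m_grid Variable-depth count thresholds (default c(5, 10, 20)).
#' @param kmax Maximum variable depth (default 6).
#' @param pooling Passed to [markov_decisions()].
#' @param mode_filter,... Passed to [markov_decisions()].
#' @param folds,chunk Passed to [markov_cv()].
#' @return A data.frame `model`, `H_bits`, `mean_history_length`.
#' @export
compare_models <- function(seq, maze, ks = 1:4, m_grid = c(5L, 10L, 20L),
                           kmax = 6L, pooling = "none", mode_filter = TRUE,
                           folds = 5L, chunk = 500L, ...) {
  dec <- markov_decisions(seq, maze, kmax = max(c(ks, kmax)),
                          pooling = pooling, mode_filter = mode_filter, ...)
  rows <- list()
  for (k in ks) {
    cv <- markov_cv(dec, depth = k, folds = folds, chunk = chunk)
    rows[[length(rows) + 1L]] <- data.frame(
      model = sprintf("fixed k=%d", k), H_bits = cv$H,
      mean_history_length = cv$mean_history_length)
  }
  for (m in m_grid) {
    cv <- markov_cv(dec, depth = NULL, kmax = kmax, m = m,
                    folds = folds, chunk = chunk)
    rows[[length(rows) + 1L]] <- data.frame(
      model = sprintf("variable m=%d", m), H_bits = cv$H,
      mean_history_length = cv$mean_history_length)
  }
  # four-bias baseline: biases estimated on the training folds
  bias_cv <- .bias_baseline_cv(dec, maze, folds, chunk)
  rows[[length(rows) + 1L]] <- data.frame(
    model = "four-bias walk", H_bits = bias_cv,
    mean_history_length = 1)
  rows[[length(rows) + 1L]] <- data.frame(
    model = "uniform", H_bits = log2(3), mean_history_length = 0)
  do.call(rbind, rows)
}

.bias_baseline_cv <- function(dec, maze, folds, chunk) {
  n <- nrow(dec)
  fold_id <- (((seq_len(n) - 1L) %/% chunk) %% folds) + 1L
  if (length(unique(fold_id)) < folds)
    fold_id <- ((seq_len(n) - 1L) %% folds) + 1L
  H <- numeric(folds)
  for (f in seq_len(folds)) {
    train <- dec[fold_id != f, , drop = FALSE]
    b <- .biases_from_decisions(train)
    H[f] <- cross_entropy(b, dec[fold_id == f, , drop = FALSE])$H
  }
  mean(H)
}

# turn decision rows (a0 + observed 3-action) into a bias_set by ML counts
.biases_from_decisions <- function(dec) {
  ok <- !is.na(dec$a0)
  a0 <- dec$a0[ok]; act <- dec$action[ok]
  stem <- a0 %in% c(0L, 1L); bar <- !stem
  fwd_s <- act != "O"
  alt <- (a0 == 0L & act == "R") | (a0 == 1L & act == "L")
  PSF <- mean(fwd_s[stem])
  PSA <- mean(alt[stem & fwd_s])
  back <- (a0 == 2L & act == "L") | (a0 == 3L & act == "R")
  PBF <- mean(!back[bar])
  PBS <- mean(act[bar & !back] == "O")
  bias_set(PSF, PSA, PBF, PBS)
}

# sequential sampler for the markov agent policy
.simulate_markov_agent <- function(model, maze, n_steps, start) {
  L <- maze$config$n_junction_levels
  kmax <- if (model$kind == "fixed") model$k else model$kmax
  pooling <- attr(model, "pooling"); if (is.null(pooling)) pooling <- "none"
  nodes <- integer(n_steps + 1L)
  nodes[1L] <- start
  labs <- character(n_steps + 1L)
  labs[1L] <- .node_labels(maze, start, pooling)
  for (i in seq_len(n_steps)) {
    cur <- nodes[i]
    if (maze$node_kind[cur + 1L] == "end_node") {
      nodes[i + 1L] <- .parent_id(cur)
    } else {
      counts <- c(L = 0, R = 0, O = 0)
      depths <- if (model$kind == "fixed") model$k else seq_len(model$kmax)
      for (j in seq_along(depths)) {
        k <- depths[j]
        if (k > i) next
        key <- paste(labs[(i - k + 1L):i], collapse = ",")
        tab <- model$tables[[j]]
        hit <- match(key, tab$hkey)
        if (!is.na(hit))
          counts <- c(L = tab$L[hit], R = tab$R[hit], O = tab$O[hit])
      }
      p <- (counts + 1) / (sum(counts) + 3)
      if (cur == 0L) {                       # confined: no exit move
        p["O"] <- 0; p <- p / sum(p)
      }
      a <- sample(c("L", "R", "O"), 1L, prob = p)
      lc <- 2L * cur + 1L
      gl <- if (.edge_gsign(cur, lc) < 0L) lc else lc + 1L   # geometric left
      nodes[i + 1L] <- switch(a, L = gl, R = if (gl == lc) lc + 1L else lc,
                              O = .parent_id(cur))
    }
    labs[i + 1L] <- .node_labels(maze, nodes[i + 1L], pooling)
  }
  nodes
}
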
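#' Greedy specification search over path-model topologies
#'
#' Starting from a fitted model, iteratively evaluates every single-edge
#' addition, deletion and reversal, accepts the move that most improves
#' the chosen information criterion, and repeats until either no move
#' improves it or the current model already meets the conventional
#' acceptance battery (non-significant chi-square, GFI > 0.95,
#' CFI > 0.95, RMSEA < 0.05). This mirrors the exploratory "modify the
#' path drawing and re-evaluate" workflow of covariance-structure
#' connectivity modelling.
#'
#' @param start a [path_model()] to start from (must be empirically
#'   identified).
#' @param moments a [sample_moments()] object or observation matrix.
#' @param candidate_edges optional data.frame (`from`, `to`) restricting
#'   which directed edges may be added (and created by reversal);
#'   default: all ordered pairs of model variables.
#' @param criterion `"aic"` or `"bic"`.
#' @param stop_on_criteria stop as soon as the acceptance battery is
#'   met (default `TRUE`).
#' @param max_steps maximum accepted moves.
#' @return list with `model` (best [path_model()]), `fit` (its
#'   [fit_ml()] with standard errors), `trace` (data.frame of every
#'   evaluated move: step, move, from, to, criterion value, accepted),
#'   and `stopped` (`"criteria"`, `"no_improvement"` or `"max_steps"`).
#' @export
specification_search <- function(start, moments, candidate_edges = NULL,
                                 criterion = c("aic", "bic"),
                                 stop_on_criteria = TRUE, max_steps = 50) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(start, "path_model"))
  if (!inherits(moments, "sample_moments")) moments <- sample_moments(moments)
  crit_of <- function(fit) if (criterion == "aic") fit$AIC else fit$BIC

  cur_fit <- fit_ml(start, moments, se = TRUE, warn_low_n = FALSE)
  if (!cur_fit$identified)
    stop("start model is empirically unidentified; search refused")
  cur_model <- as_plain_model(start)
  cur_crit <- crit_of(cur_fit)

  vars <- cur_model$variables
  if (is.null(candidate_edges)) {
    candidate_edges <- expand.grid(from = vars, to = vars,
                                   stringsAsFactors = FALSE)
    candidate_edges <- candidate_edges[candidate_edges$from !=
                                         candidate_edges$to, ]
  } else {
    candidate_edges <- as.data.frame(candidate_edges)
    if (!all(c(candidate_edges$from, candidate_edges$to) %in% vars))
      stop_validation("candidate_edges mention unknown variables")
    candidate_edges <- candidate_edges[candidate_edges$from !=
                                         candidate_edges$to, ]
  }
  edge_key <- function(df) paste(df$from, df$to, sep = "\r")

  trace <- list()
  step <- 0L
  stopped <- "no_improvement"
  repeat {
    if (stop_on_criteria && meets_fit_criteria(cur_fit)) {
      stopped <- "criteria"
      break
    }
    if (step >= max_steps) {
      stopped <- "max_steps"
      break
    }
    moves <- propose_moves(cur_model, candidate_edges, edge_key)
    if (!nrow(moves)) break
    vals <- rep(NA_real_, nrow(moves))
    n_free <- rep(NA_integer_, nrow(moves))
    for (i in seq_len(nrow(moves))) {
      cand <- tryCatch(apply_move(cur_model, moves[i, ]),
                       error = function(e) NULL)
      if (is.null(cand)) next
      f <- tryCatch(
        suppressWarnings(fit_ml(cand, moments, se = FALSE,
                                warn_low_n = FALSE)),
        error = function(e) NULL)
      if (!is.null(f) && f$converged) {
        vals[i] <- crit_of(f)
        n_free[i] <- model_n_free(cand)
      }
    }
    moves$criterion <- vals
    moves$step <- step + 1L
    moves$accepted <- FALSE
    improving <- which(is.finite(vals) & vals < cur_crit - 1e-9)
    if (!length(improving)) {
      trace[[length(trace) + 1L]] <- moves
      break
    }
    # ties: fewest parameters, then lexicographic edge order
    best <- improving[order(vals[improving], n_free[improving],
                            moves$from[improving], moves$to[improving])][1]
    moves$accepted[best] <- TRUE
    trace[[length(trace) + 1L]] <- moves
    cur_model <- apply_move(cur_model, moves[best, ])
    cur_fit <- suppressWarnings(fit_ml(cur_model, moments, se = FALSE,
                                       warn_low_n = FALSE))
    cur_crit <- crit_of(cur_fit)
    step <- step + 1L
  }
  final_fit <- suppressWarnings(fit_ml(cur_model, moments, se = TRUE,
                                       warn_low_n = FALSE))
  list(model = cur_model, fit = final_fit,
       trace = if (length(trace)) do.call(rbind, trace)
               else data.frame(move = character(), from = character(),
                               to = character(), criterion = numeric(),
                               step = integer(), accepted = logical()),
       stopped = stopped)
}

as_plain_model <- function(model) {
  path_model(model$variables, model$paths[c("from", "to")],
             psi_pairs = model$psi_pairs)
}

propose_moves <- function(model, candidate_edges, edge_key) {
  cur <- edge_key(model$paths)
  add <- candidate_edges[!(edge_key(candidate_edges) %in% cur), ,
                         drop = FALSE]
  moves <- data.frame(move = character(), from = character(),
                      to = character())
  if (nrow(add))
    moves <- rbind(moves, data.frame(move = "add", from = add$from,
                                     to = add$to))
  if (nrow(model$paths)) {
    moves <- rbind(moves, data.frame(move = "delete",
                                     from = model$paths$from,
                                     to = model$paths$to))
    rev <- model$paths[c("from", "to")]
    ok <- !(paste(rev$to, rev$from, sep = "\r") %in% cur) &
      (paste(rev$to, rev$from, sep = "\r") %in% edge_key(candidate_edges))
    if (any(ok))
      moves <- rbind(moves, data.frame(move = "reverse",
                                       from = rev$from[ok],
                                       to = rev$to[ok]))
  }
  moves
}

apply_move <- function(model, move) {
  paths <- model$paths[c("from", "to")]
  if (move$move == "add") {
    paths <- rbind(paths, data.frame(from = move$from, to = move$to))
  } else if (move$move == "delete") {
    paths <- paths[!(paths$from == move$from & paths$to == move$to), ]
  } else {  # reverse
    paths <- paths[!(paths$from == move$from & paths$to == move$to), ]
    paths <- rbind(paths, data.frame(from = move$to, to = move$from))
  }
  path_model(model$variables, paths, psi_pairs = model$psi_pairs)
}
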
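#' Construct a population-tree demographic model
#'
#' A model is a rooted population tree: one branch per population with a
#' constant scaled diploid size `lambda = N / n_ref`, a haploid sample
#' size contributed at the tips, and an optional sample age (scaled time
#' at which the samples lived; ancient samples enter the coalescent only
#' at their age). Joins are backward-in-time mergers: at `time` all
#' lineages of branch `from` move into branch `into`, which may take a
#' new size `lambda_after` for the ancestral segment. A branch may absorb
#' several joins and so carries a piecewise-constant size along the tree
#' spine.
#'
#' @param branches A data frame with columns `name`, `lambda`,
#'   `sample_size` and optionally `sample_age` (default 0).
#' @param joins A data frame with columns `time`, `into`, `from` and
#'   optionally `lambda_after` (default `NA`, keep current size). Ties in
#'   time are allowed and applied in row order.
#' @return An object of class `demography`.
#' @examples
#' m <- demography(
#'   branches = tibble::tibble(name = c("A", "B"), lambda = c(1, 0.5),
#'                             sample_size = c(4, 4)),
#'   joins = tibble::tibble(time = 0.002, into = "A", from = "B",
#'                          lambda_after = 2)
#' )
#' validate_demography(m)
#' @export
demography <- function(branches, joins) {
  branches <- tibble::as_tibble(branches)
  if (!"sample_age" %in% names(branches)) branches$sample_age <- 0
  branches$sample_age[is.na(branches$sample_age)] <- 0
  branches <- branches[, c("name", "lambda", "sample_size", "sample_age")]
  branches$name <- as.character(branches$name)
  if (missing(joins) || is.null(joins) || nrow(joins) == 0) {
    joins <- tibble::tibble(time = numeric(), into = character(),
                            from = character(), lambda_after = numeric())
  } else {
    joins <- tibble::as_tibble(joins)
    if (!"lambda_after" %in% names(joins)) joins$lambda_after <- NA_real_
    joins <- joins[, c("time", "into", "from", "lambda_after")]
    joins$into <- as.character(joins$into)
    joins$from <- as.character(joins$from)
    # stable sort by time; file/row order breaks ties
    joins <- joins[order(joins$time), , drop = FALSE]
  }
  structure(list(branches = branches, joins = joins), class = "demography")
}

#' Validate a demographic model
#'
#' Checks every structural invariant: positive sizes, non-negative sample
#' sizes and ages, positive join times, that the joins form a single
#' rooted tree (K - 1 joins for K branches, each branch absorbed at most
#' once, both partners alive at each join), and that every sample age
#' strictly precedes the first join involving its branch.
#'
#' @param m A `demography`.
#' @return A character vector of violations; `character(0)` means valid.
#' @export
validate_demography <- function(m) {
  v <- character()
  b <- m$branches
  j <- m$joins
  if (anyDuplicated(b$name)) v <- c(v, "duplicate branch names")
  if (any(b$lambda <= 0)) v <- c(v, "branch lambda must satisfy lambda > 0")
  if (any(b$sample_size < 0)) v <- c(v, "sample_size must be >= 0")
  if (any(b$sample_age < 0)) v <- c(v, "sample_age must be >= 0")
  if (nrow(j) != nrow(b) - 1)
    v <- c(v, sprintf("not a rooted tree: %d branches need %d joins, found %d",
                      nrow(b), nrow(b) - 1, nrow(j)))
  if (nrow(j) > 0) {
    if (any(j$time <= 0)) v <- c(v, "join time must satisfy time > 0")
    if (any(j$into == j$from)) v <- c(v, "join with into == from")
    unknown <- setdiff(c(j$into, j$from), b$name)
    if (length(unknown))
      v <- c(v, paste("unknown branch label:", paste(unknown, collapse = ", ")))
    if (!is.na(d <- anyDuplicated(j$from)) && d > 0)
      v <- c(v, "a branch is absorbed ('from') more than once")
  }
  if (length(v)) return(v)

  # replay joins in time order (stable: row order breaks ties);
  # both partners must be alive; 'from' dies
  alive <- stats::setNames(rep(TRUE, nrow(b)), b$name)
  for (i in order(j$time)) {
    if (!alive[[j$into[i]]])
      v <- c(v, sprintf("join %d: branch '%s' already absorbed", i, j$into[i]))
    if (!alive[[j$from[i]]])
      v <- c(v, sprintf("join %d: branch '%s' already absorbed", i, j$from[i]))
    alive[[j$from[i]]] <- FALSE
  }
  if (length(v)) return(v)
  if (sum(alive) != 1) v <- c(v, "not a rooted tree: more than one root remains")

  # sample ages strictly before the first join involving the branch
  for (k in seq_len(nrow(b))) {
    if (b$sample_age[k] <= 0) next
    touch <- j$time[j$into == b$name[k] | j$from == b$name[k]]
    if (length(touch) && b$sample_age[k] >= min(touch))
      v <- c(v, sprintf("branch '%s': sample_age %g not before its first join at %g",
                        b$name[k], b$sample_age[k], min(touch)))
  }
  v
}

root_branch <- function(m) {
  setdiff(m$branches$name, m$joins$from)
}

#' @export
print.demography <- function(x, ...) {
  cat(sprintf("<demography> %d branches, %d joins\n",
              nrow(x$branches), nrow(x$joins)))
  print(x$branches)
  if (nrow(x$joins)) print(x$joins)
  invisible(x)
}

#' Convert a model to real units
#'
#' @param m A `demography`.
#' @param scale A [unit_scale()].
#' @return A tibble reporting join (split) times in years and branch
#'   segment sizes in diploids.
#' @examples
#' m <- demography(tibble::tibble(name = c("A", "B"), lambda = c(1, 0.6),
#'                                sample_size = c(2, 2)),
#'                 tibble::tibble(time = 0.003, into = "A", from = "B"))
#' to_real(m, unit_scale()) # 0.003 * 40000 * 29 = 3480 years
#' @export
to_real <- function(m, scale = unit_scale()) {
  b <- m$branches
  j <- m$joins
  out <- tibble::tibble(
    quantity = c(rep("branch_size", nrow(b)),
                 rep("split_time", nrow(j)),
                 rep("ancestral_size", sum(!is.na(j$lambda_after)))),
    name = c(b$name,
             paste(j$into, j$from, sep = "/"),
             paste0(j$into, " (after ", j$into, "/", j$from,
                    ")")[!is.na(j$lambda_after)]),
    scaled = c(b$lambda, j$time, j$lambda_after[!is.na(j$lambda_after)])
  )
  out$real <- ifelse(out$quantity == "split_time",
                     scaled_to_years(out$scaled, scale),
                     out$scaled * scale$n_ref)
  out$unit <- ifelse(out$quantity == "split_time", "years", "diploids")
  out
}

#' Read a demographic model from its text format
#'
#' One directive per line, `#` starts a comment:
#' \preformatted{
#' branch <name> <lambda> <sample_size> [<sample_age>]
#' join <time> <into> <from> [<lambda_after>]
#' scale <n_ref> <mu> <gen_years>
#' }
#'
#' @param path File path, or a character vector of lines via `text =`.
#' @param text Optional literal text (overrides `path`).
#' @return A `demography`; if a `scale` directive is present the
#'   corresponding [unit_scale()] is attached as attribute `"scale"`.
#' @export
read_demography <- function(path, text = NULL) {
  lines <- if (!is.null(text)) unlist(strsplit(text, "\n")) else readLines(path)
  branches <- list(); joins <- list(); scale <- NULL
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    if (!nzchar(trimws(ln))) next
    tok <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    bad <- function(what) stop(sprintf("line %d: %s in '%s'", i, what, lines[i]),
                               call. = FALSE)
    num <- function(s) {
      x <- suppressWarnings(as.numeric(s))
      if (is.na(x)) bad(paste("bad number", s))
      x
    }
    if (tok[1] == "branch") {
      if (!(length(tok) %in% 4:5)) bad("branch needs 3-4 fields")
      branches[[length(branches) + 1]] <- tibble::tibble(
        name = tok[2], lambda = num(tok[3]), sample_size = num(tok[4]),
        sample_age = if (length(tok) == 5) num(tok[5]) else 0)
    } else if (tok[1] == "join") {
      if (!(length(tok) %in% 4:5)) bad("join needs 3-4 fields")
      joins[[length(joins) + 1]] <- tibble::tibble(
        time = num(tok[2]), into = tok[3], from = tok[4],
        lambda_after = if (length(tok) == 5) num(tok[5]) else NA_real_)
    } else if (tok[1] == "scale") {
      if (length(tok) != 4) bad("scale needs 3 fields")
      if (!is.null(scale)) bad("duplicate scale directive")
      scale <- unit_scale(num(tok[2]), num(tok[3]), num(tok[4]))
    } else bad(paste("unknown directive", tok[1]))
  }
  if (!length(branches)) stop("no branch directives found")
  bt <- dplyr::bind_rows(branches)
  if (anyDuplicated(bt$name))
    stop("duplicate branch directive for: ",
         paste(unique(bt$name[duplicated(bt$name)]), collapse = ", "))
  m <- demography(bt, if (length(joins)) dplyr::bind_rows(joins) else NULL)
  v <- validate_demography(m)
  if (length(v)) stop("invalid model: ", paste(v, collapse = "; "))
  if (!is.null(scale)) attr(m, "scale") <- scale
  m
}

#' Write a demographic model in its text format
#'
#' @param m A `demography`.
#' @param path Optional file path; if omitted the lines are returned.
#' @param scale Optional [unit_scale()] to record as a `scale` directive.
#' @return Invisibly, the character vector of lines.
#' @export
write_demography <- function(m, path = NULL, scale = attr(m, "scale")) {
  b <- m$branches
  lines <- sprintf("branch %s %.10g %d %.10g", b$name, b$lambda,
                   as.integer(b$sample_size), b$sample_age)
  lines <- sub(" 0$", "", lines) # drop default age
  j <- m$joins
  if (nrow(j)) {
    jl <- ifelse(is.na(j$lambda_after),
                 sprintf("join %.10g %s %s", j$time, j$into, j$from),
                 sprintf("join %.10g %s %s %.10g", j$time, j$into, j$from,
                         j$lambda_after))
    lines <- c(lines, jl)
  }
  if (!is.null(scale))
    lines <- c(lines, sprintf("scale %.10g %.10g %.10g",
                              scale$n_ref, scale$mu, scale$gen_years))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

# ---- free-parameter mapping ------------------------------------------------

#' Map free parameters of a model to an unconstrained vector
#'
#' Sizes (`lambda:<branch>` for tips, `alambda:<i>` for the ancestral
#' segment created by join `i`, or `alambda:all` for one size shared by
#' every ancestral segment) and join times are fitted on the log scale.
#' Join times (`time:<i>`, with `i` indexing the joins) are
#' reparameterized as positive increments over the latest earlier event
#' involving either partner branch, which makes every parameter vector a
#' valid tree without rejection steps.
#'
#' @param m A `demography` template.
#' @param free Character vector of slot names as above.
#' @param lower,upper Optional named bounds on the natural scale.
#' @return An object of class `param_map`.
#' @export
param_map <- function(m, free, lower = NULL, upper = NULL) {
  known <- c(paste0("lambda:", m$branches$name),
             if (nrow(m$joins)) paste0("time:", seq_len(nrow(m$joins))),
             if (nrow(m$joins)) paste0("alambda:", seq_len(nrow(m$joins))),
             if (nrow(m$joins)) "alambda:all")
  bad <- setdiff(free, known)
  if (length(bad)) stop("unknown parameter slot(s): ", paste(bad, collapse = ", "))
  kind <- sub(":.*$", "", free)
  def_lo <- ifelse(kind == "time", 1e-8, 1e-4)
  def_hi <- ifelse(kind == "time", 10, 1e4)
  lo <- stats::setNames(def_lo, free)
  hi <- stats::setNames(def_hi, free)
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(lo >= hi))
    stop("bounds must be finite and ordered")
  # all parameters are fitted on the log scale: sizes are positive by
  # nature and join-time increments by construction, and a common scale
  # keeps the simplex/proposal geometry well conditioned
  structure(list(template = m, names = free, kind = kind,
                 transform = rep("log", length(free)),
                 lower = lo, upper = hi),
            class = "param_map")
}

# base time for join i: latest earlier event involving either partner
join_base_times <- function(m) {
  j <- m$joins
  last_ev <- stats::setNames(rep(0, nrow(m$branches)), m$branches$name)
  for (k in seq_len(nrow(m$branches)))
    last_ev[[m$branches$name[k]]] <- m$branches$sample_age[k]
  base <- numeric(nrow(j))
  for (i in seq_len(nrow(j))) {
    base[i] <- max(last_ev[[j$into[i]]], last_ev[[j$from[i]]])
    last_ev[[j$into[i]]] <- j$time[i]
  }
  base
}

# natural-scale parameter values of the template (times as increments)
pmap_init <- function(pm) {
  m <- pm$template
  base <- join_base_times(m)
  vapply(seq_along(pm$names), function(i) {
    nm <- pm$names[i]
    idx <- sub("^[a-z]+:", "", nm)
    switch(pm$kind[i],
           lambda = m$branches$lambda[m$branches$name == idx],
           time = m$joins$time[as.integer(idx)] - base[as.integer(idx)],
           alambda = {
             v <- if (idx == "all") m$joins$lambda_after[1] else
               m$joins$lambda_after[as.integer(idx)]
             if (is.na(v)) 1 else v
           })
  }, numeric(1))
}

pmap_to_transformed <- function(pm, x) ifelse(pm$transform == "log", log(x), x)
pmap_from_transformed <- function(pm, y) ifelse(pm$transform == "log", exp(y), y)

# apply natural-scale free values to the template; returns model or NULL
# when outside bounds / invalid
pmap_apply <- function(pm, x) {
  if (any(!is.finite(x)) || any(x < pm$lower) || any(x > pm$upper)) return(NULL)
  m <- pm$template
  incr <- stats::setNames(rep(NA_real_, nrow(m$joins)),
                          seq_len(max(nrow(m$joins), 0)))
  for (i in seq_along(pm$names)) {
    nm <- pm$names[i]
    idx <- sub("^[a-z]+:", "", nm)
    if (pm$kind[i] == "lambda") {
      m$branches$lambda[m$branches$name == idx] <- x[i]
    } else if (pm$kind[i] == "alambda") {
      if (idx == "all") m$joins$lambda_after[] <- x[i]
      else m$joins$lambda_after[as.integer(idx)] <- x[i]
    } else {
      incr[[idx]] <- x[i]
    }
  }
  if (nrow(m$joins)) {
    # rebuild join times in order: free ones as base + increment,
    # fixed ones keep their absolute time (must remain consistent)
    last_ev <- stats::setNames(m$branches$sample_age, m$branches$name)
    for (i in seq_len(nrow(m$joins))) {
      base <- max(last_ev[[m$joins$into[i]]], last_ev[[m$joins$from[i]]])
      if (!is.na(incr[[as.character(i)]])) {
        m$joins$time[i] <- base + incr[[as.character(i)]]
      } else if (m$joins$time[i] <= base) {
        return(NULL)
      }
      last_ev[[m$joins$into[i]]] <- m$joins$time[i]
    }
    # joins stay in template row order (a linear extension of the tree's
    # partial order) so slot indices remain stable; consumers sort by time
  }
  if (length(validate_demography(m))) return(NULL)
  m
}

# named natural-scale slot values (actual join times, not increments)
pmap_slot_values <- function(pm, x) {
  m <- pmap_apply(pm, x)
  if (is.null(m)) return(stats::setNames(rep(NA_real_, length(pm$names)), pm$names))
  vapply(seq_along(pm$names), function(i) {
    idx <- sub("^[a-z]+:", "", pm$names[i])
    switch(pm$kind[i],
           lambda = m$branches$lambda[m$branches$name == idx],
           time = m$joins$time[as.integer(idx)],
           alambda = if (idx == "all") m$joins$lambda_after[1] else
             m$joins$lambda_after[as.integer(idx)])
  }, numeric(1)) |> stats::setNames(pm$names)
}
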
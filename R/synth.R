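# Synthetic nanopub corpora with controlled marginals, controlled
# prediction perturbations, and paired annotator labelings at a target
# kappa. Category counts are met by exact quota sampling (largest-remainder
# apportionment + seeded shuffling), not i.i.d. draws, so marginal
# assertions in tests are exact and never flaky.

#' Configuration of the synthetic corpus generator
#'
#' Defaults emulate the published training-corpus marginals: about 1.74
#' statements per sentence, 87/8/4/1 percent protein/chemical/process/
#' pathology term occurrences, 0.83 function occurrences per statement
#' distributed 69/15.5/8.2/4.5/2.3/0.4/0.1 percent over
#' act/pmod/complex/tloc/deg/sub/trunc, and 73 percent increases
#' relationships. Entity names use reserved synthetic vocabularies
#' (HGNC:GENE0001, MGI:Gene0001, CHEBI:chem0001, quoted GOBP/MESHD names)
#' so they cannot collide with real symbols. Evidence text embeds the
#' entity surface forms and a polarity trigger word, so retrieval tests can
#' reuse generated corpora.
#'
#' @param n_sentences Number of evidence sentences.
#' @param two_statement_share Share of sentences carrying two statements
#'   (the rest carry one).
#' @param term_shares Named shares for term-type occurrences
#'   (`P`, `A`, `bp`, `path`), summing to 1.
#' @param function_rate Function occurrences per statement.
#' @param function_shares Named shares over
#'   `act`, `pmod`, `complex`, `tloc`, `deg`, `sub`, `trunc`, summing to 1.
#' @param increases_share Share of `increases`-polarity relationships.
#' @param direct_share Share of each polarity rendered as the `directly*`
#'   variant.
#' @param vocab_size Entity vocabulary size per namespace.
#' @param seed Integer seed fixing all randomness.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_sentences = 100L,
                         two_statement_share = 0.74,
                         term_shares = c(P = 0.87, A = 0.08, bp = 0.04,
                                         path = 0.01),
                         function_rate = 0.83,
                         function_shares = c(act = 0.69, pmod = 0.155,
                                             complex = 0.082, tloc = 0.045,
                                             deg = 0.023, sub = 0.004,
                                             trunc = 0.001),
                         increases_share = 0.73,
                         direct_share = 0.25,
                         vocab_size = 500L,
                         seed = 1L) {
  stopifnot(n_sentences >= 1,
            abs(sum(term_shares) - 1) < 1e-8, all(term_shares >= 0),
            abs(sum(function_shares) - 1) < 1e-8, all(function_shares >= 0),
            increases_share >= 0, increases_share <= 1,
            two_statement_share >= 0, two_statement_share <= 1)
  stopifnot(identical(sort(names(term_shares)), sort(c("P", "A", "bp", "path"))),
            identical(sort(names(function_shares)),
                      sort(c("act", "pmod", "complex", "tloc", "deg", "sub",
                             "trunc"))))
  structure(
    list(n_sentences = as.integer(n_sentences),
         two_statement_share = two_statement_share,
         term_shares = term_shares[c("P", "A", "bp", "path")],
         function_rate = function_rate,
         function_shares = function_shares[c("act", "pmod", "complex", "tloc",
                                             "deg", "sub", "trunc")],
         increases_share = increases_share,
         direct_share = direct_share,
         vocab_size = as.integer(vocab_size),
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

.synth_triggers <- list(
  increases = c("increases", "induces", "enhances", "upregulates"),
  decreases = c("decreases", "inhibits", "suppresses", "reduces")
)

# one entity per slot type; surface form is the bare name
synth_entity <- function(type, id) {
  switch(type,
    P_HGNC = bel_entity("HGNC", sprintf("GENE%04d", id)),
    P_MGI = bel_entity("MGI", sprintf("Gene%04d", id)),
    A = bel_entity("CHEBI", sprintf("chem%04d", id)),
    bp = bel_entity("GOBP", sprintf("process %04d", id)),
    path = bel_entity("MESHD", sprintf("disease %04d", id))
  )
}

#' Generate a synthetic nanopub corpus
#'
#' Builds a corpus record data.frame whose term-, function- and
#' relationship-type counts match the configured quotas exactly; every
#' statement parses and validates, evidence strings contain the entity
#' names and a polarity trigger and stay within the 36--425 character
#' corpus-selection bounds, and the whole corpus is a deterministic
#' function of the seed.
#'
#' @param config A [synth_config()].
#' @return A corpus record data.frame (columns as [read_corpus_tab()]).
#' @export
#' @examples
#' corpus <- gen_corpus(synth_config(n_sentences = 10, seed = 42))
#' nrow(corpus_stats(corpus)$terms)
gen_corpus <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    n_sent <- config$n_sentences
    n_two <- round(config$two_statement_share * n_sent)
    sent_sizes <- shuffle(c(rep(2L, n_two), rep(1L, n_sent - n_two)))
    n_stmt <- sum(sent_sizes)

    # relationships: exact polarity quota, then exact directly* quota within
    rel_counts <- apportion(n_stmt, c(increases = config$increases_share,
                                      decreases = 1 - config$increases_share))
    make_rels <- function(base, n) {
      n_direct <- round(config$direct_share * n)
      shuffle(c(rep(paste0("directly", toupper(substr(base, 1, 1)),
                           substr(base, 2, nchar(base))), n_direct),
                rep(base, n - n_direct)))
    }
    rels <- shuffle(c(make_rels("increases", rel_counts["increases"]),
                      make_rels("decreases", rel_counts["decreases"])))

    # function occurrence quotas
    n_func <- round(config$function_rate * n_stmt)
    fcounts <- apportion(n_func, config$function_shares)
    n_complex <- fcounts[["complex"]]

    # term-occurrence quotas over 2 slots/statement, complex slots carrying
    # two protein entities each
    n_slots <- 2L * n_stmt
    total_occ <- n_slots + n_complex
    tcounts <- apportion(total_occ, config$term_shares)
    n_plain_p <- tcounts[["P"]] - 2L * n_complex
    if (n_plain_p < 0) {
      stop("infeasible quotas: complex quota requires more protein terms than the term shares provide",
           call. = FALSE)
    }
    slot_types <- shuffle(c(rep("complex", n_complex),
                           rep("P", n_plain_p),
                           rep("A", tcounts[["A"]]),
                           rep("bp", tcounts[["bp"]]),
                           rep("path", tcounts[["path"]])))

    # assign one decoration per slot, most constrained ops first
    deco <- rep("none", n_slots)
    assign_op <- function(op, n, eligible) {
      if (n == 0) return(invisible(NULL))
      open <- which(deco == "none" & eligible)
      if (length(open) < n) {
        stop(sprintf("infeasible quotas: %d %s occurrences but only %d eligible slots",
                     n, op, length(open)), call. = FALSE)
      }
      deco[shuffle(open)[seq_len(n)]] <<- op
      invisible(NULL)
    }
    is_p <- slot_types == "P"
    is_pa <- slot_types %in% c("P", "A")
    assign_op("pmod", fcounts[["pmod"]], is_p)
    assign_op("sub", fcounts[["sub"]], is_p)
    assign_op("trunc", fcounts[["trunc"]], is_p)
    assign_op("tloc", fcounts[["tloc"]], is_pa)
    assign_op("deg", fcounts[["deg"]], is_pa)
    assign_op("act", fcounts[["act"]], is_p | slot_types == "complex")

    # build one term per slot
    act_cycle <- c("act", "kin", "cat", "tscript")
    vocab <- config$vocab_size
    pick_id <- function() sample.int(vocab, 1L)
    base_term <- function(type) {
      switch(type,
        P = {
          ns <- if (stats::runif(1) < 0.5) "P_HGNC" else "P_MGI"
          bel_term("p", entity = synth_entity(ns, pick_id()))
        },
        A = bel_term("a", entity = synth_entity("A", pick_id())),
        bp = bel_term("bp", entity = synth_entity("bp", pick_id())),
        path = bel_term("path", entity = synth_entity("path", pick_id())),
        complex = bel_term("complex", args = list(
          bel_term("p", entity = synth_entity("P_HGNC", pick_id())),
          bel_term("p", entity = synth_entity("P_MGI", pick_id()))
        ))
      )
    }
    slot_no <- 0L
    build_slot <- function(type, op) {
      slot_no <<- slot_no + 1L
      t <- base_term(type)
      switch(op,
        none = t,
        pmod = {
          # alternate between bare and fully specified pmod arguments
          m <- if (slot_no %% 2 == 0) bel_mod("pmod", type = "P") else
            bel_mod("pmod", type = "P", residue = "T", position = 202L)
          t$mods <- list(m); t
        },
        sub = { t$mods <- list(bel_mod("sub", ref = "E", position = 545L,
                                       alt = "K")); t },
        trunc = { t$mods <- list(bel_mod("trunc", position = 1851L)); t },
        act = bel_term(act_cycle[slot_no %% length(act_cycle) + 1L],
                       args = list(t)),
        tloc = {
          locs <- if (slot_no %% 2 == 0) list() else
            list(bel_entity("GOCC", "cytoplasm"), bel_entity("GOCC", "nucleus"))
          bel_term("tloc", args = list(t), locations = locs)
        },
        deg = bel_term("deg", args = list(t))
      )
    }
    terms <- mapply(build_slot, slot_types, deco, SIMPLIFY = FALSE)

    statements <- lapply(seq_len(n_stmt), function(i) {
      bel_statement(terms[[2L * i - 1L]], rels[i], terms[[2L * i]])
    })

    # evidence text: one clause per statement, entity surfaces + trigger
    first_name <- function(term) {
      e <- collect_entities(term)[1]
      sub("^[^:]+:", "", gsub("\"", "", e))
    }
    clause <- function(s, i) {
      pol <- if (grepl("ncreases$", s$rel)) "increases" else "decreases"
      trig <- .synth_triggers[[pol]][i %% 4L + 1L]
      sprintf("%s markedly %s %s", first_name(s$subject), trig,
              first_name(s$object))
    }
    stmt_idx <- 1L
    rows <- vector("list", n_sent)
    for (si in seq_len(n_sent)) {
      k <- sent_sizes[si]
      idx <- stmt_idx:(stmt_idx + k - 1L)
      stmt_idx <- stmt_idx + k
      clauses <- vapply(seq_along(idx),
                        function(j) clause(statements[[idx[j]]], idx[j]), "")
      text <- sprintf("In these experiments, %s in a dose-dependent manner.",
                      paste(clauses, collapse = ", and "))
      rows[[si]] <- new_df(
        bel_id = sprintf("B%05d", idx),
        statement = vapply(statements[idx], render_bel, ""),
        sentence_id = rep(sprintf("S%05d", si), k),
        sentence = rep(text, k),
        pmid = rep(sprintf("%d", 10000000L + si), k)
      )
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Perturbation specification for synthetic predictions
#'
#' Each operation is applied to a disjoint, exactly quota-sized subset of
#' eligible records (rate times the record count, rounded), so expected
#' tp/fp/fn are computable from the manifest without Monte-Carlo error.
#'
#' @param flip_relationship Rate of polarity flips (increases <->
#'   decreases).
#' @param swap_entity Rate of replacing one entity with an unseen one.
#' @param drop_function Rate of removing one function decoration (only
#'   records that have one are eligible).
#' @param alter_pmod_args Rate of adding residue/position arguments to a
#'   pmod (a no-op under full simplification; only pmod carriers eligible).
#' @param drop_statement Rate of omitting the statement from the
#'   prediction.
#' @param add_statement Rate of adding a spurious statement to a sentence.
#' @param seed Integer seed.
#' @return An object of class `perturb_spec`.
#' @export
perturb_spec <- function(flip_relationship = 0, swap_entity = 0,
                         drop_function = 0, alter_pmod_args = 0,
                         drop_statement = 0, add_statement = 0, seed = 1L) {
  rates <- c(flip_relationship = flip_relationship, swap_entity = swap_entity,
             drop_function = drop_function, alter_pmod_args = alter_pmod_args,
             drop_statement = drop_statement, add_statement = add_statement)
  stopifnot(all(rates >= 0), all(rates <= 1))
  structure(list(rates = rates, seed = as.integer(seed)),
            class = "perturb_spec")
}

replace_first_entity <- function(term, entity) {
  if (!is.null(term$entity)) {
    term$entity <- entity
    return(list(term = term, done = TRUE))
  }
  for (i in seq_along(term$args)) {
    r <- replace_first_entity(term$args[[i]], entity)
    if (r$done) {
      term$args[[i]] <- r$term
      return(list(term = term, done = TRUE))
    }
  }
  list(term = term, done = FALSE)
}

has_droppable_function <- function(s) {
  wrapper <- function(t) t$fn %in% c(.bel_activity_fns, "tloc", "sec", "surf", "deg")
  wrapper(s$subject) || (is_bel_term(s$object) && wrapper(s$object)) ||
    length(s$subject$mods) > 0 ||
    (is_bel_term(s$object) && length(s$object$mods) > 0)
}

has_pmod <- function(s) {
  any(collect_mod_kinds(s) == "pmod")
}

flip_rel <- function(rel) {
  c(increases = "decreases", decreases = "increases",
    directlyIncreases = "directlyDecreases",
    directlyDecreases = "directlyIncreases")[[rel]]
}

drop_one_function <- function(s) {
  wrapper <- function(t) t$fn %in% c(.bel_activity_fns, "tloc", "sec", "surf", "deg")
  if (wrapper(s$subject)) {
    s$subject <- s$subject$args[[1]]
  } else if (is_bel_term(s$object) && wrapper(s$object)) {
    s$object <- s$object$args[[1]]
  } else if (length(s$subject$mods) > 0) {
    s$subject$mods <- list()
  } else if (is_bel_term(s$object)) {
    s$object$mods <- list()
  }
  s
}

alter_pmod <- function(t) {
  if (is_bel_statement(t)) {
    t$subject <- alter_pmod(t$subject)
    t$object <- alter_pmod(t$object)
    return(t)
  }
  t$mods <- lapply(t$mods, function(m) {
    if (m$kind == "pmod" && is.null(m$residue)) {
      bel_mod("pmod", type = m$type, residue = "S", position = 41L)
    } else m
  })
  t$args <- lapply(t$args, alter_pmod)
  t
}

#' Perturb a gold corpus into a controlled prediction set
#'
#' Applies the operations of `spec` to disjoint record subsets and returns
#' the resulting prediction annotation set together with a manifest of the
#' edit applied to every record. With one statement per sentence (and
#' distinct statements), expected cascade counts follow exactly from the
#' manifest via [perturb_expected_counts()].
#'
#' @param records A corpus record data.frame (e.g. from [gen_corpus()]).
#' @param spec A [perturb_spec()].
#' @return A list with `predicted` (data.frame `sentence_id`, `statement`)
#'   and `manifest` (data.frame `bel_id`, `sentence_id`, `op`; one row per
#'   gold record plus one per added statement).
#' @export
perturb <- function(records, spec = perturb_spec()) {
  stopifnot(inherits(spec, "perturb_spec"))
  n <- nrow(records)
  parsed <- lapply(records$statement, parse_bel_statement)
  with_seed(spec$seed, {
    op <- rep("none", n)
    eligible <- list(
      alter_pmod_args = vapply(parsed, has_pmod, TRUE),
      drop_function = vapply(parsed, has_droppable_function, TRUE),
      flip_relationship = rep(TRUE, n),
      swap_entity = rep(TRUE, n),
      drop_statement = rep(TRUE, n)
    )
    for (name in names(eligible)) {
      quota <- round(spec$rates[[name]] * n)
      open <- which(op == "none" & eligible[[name]])
      quota <- min(quota, length(open))
      if (quota > 0) {
        op[shuffle(open)[seq_len(quota)]] <- name
      }
    }
    novel <- 0L
    fresh_entity <- function() {
      novel <<- novel + 1L
      bel_entity("HGNC", sprintf("NOVEL%04d", novel))
    }
    pred_rows <- vector("list", n)
    for (i in seq_len(n)) {
      s <- parsed[[i]]
      s2 <- switch(op[i],
        none = s,
        flip_relationship = { s$rel <- flip_rel(s$rel); s },
        swap_entity = {
          r <- replace_first_entity(s$subject, fresh_entity())
          s$subject <- r$term; s
        },
        drop_function = drop_one_function(s),
        alter_pmod_args = alter_pmod(s),
        drop_statement = NULL
      )
      if (!is.null(s2)) {
        pred_rows[[i]] <- new_df(sentence_id = records$sentence_id[i],
                                 statement = render_bel(s2))
      }
    }
    manifest <- new_df(bel_id = records$bel_id,
                       sentence_id = records$sentence_id, op = op)
    n_add <- round(spec$rates[["add_statement"]] * n)
    if (n_add > 0) {
      sids <- unique(records$sentence_id)
      target <- shuffle(sids)[seq_len(min(n_add, length(sids)))]
      for (j in seq_along(target)) {
        stmt <- bel_statement(
          bel_term("p", entity = fresh_entity()), "increases",
          bel_term("p", entity = fresh_entity()))
        pred_rows[[n + j]] <- new_df(sentence_id = target[j],
                                     statement = render_bel(stmt))
        manifest <- rbind(manifest, new_df(
          bel_id = sprintf("ADD%04d", j), sentence_id = target[j],
          op = "add_statement"))
      }
    }
    list(predicted = do.call(rbind, pred_rows), manifest = manifest)
  })
}

#' Expected statement-level counts from a perturbation manifest
#'
#' Derives the statement-level tp/fp/fn that [score_bel()] must report for
#' a perturbed prediction set, assuming one statement per sentence (or, in
#' general, no unit collisions between distinct statements of a sentence)
#' and full simplification (so `alter_pmod_args` is a no-op).
#'
#' @param manifest The manifest data.frame from [perturb()].
#' @return A list with `tp`, `fp`, `fn`, `precision`, `recall`, `f`.
#' @export
perturb_expected_counts <- function(manifest) {
  op <- manifest$op
  wrong <- c("flip_relationship", "swap_entity", "drop_function")
  tp <- sum(op %in% c("none", "alter_pmod_args"))
  fp <- sum(op %in% wrong) + sum(op == "add_statement")
  fn <- sum(op %in% wrong) + sum(op == "drop_statement")
  m <- prf(tp, fp, fn)
  list(tp = tp, fp = fp, fn = fn,
       precision = m[["precision"]], recall = m[["recall"]], f = m[["f"]])
}

#' Generate a pair of annotator label sequences at a target kappa
#'
#' Draws paired binary labels from the 2x2 distribution with common
#' marginal `prevalence` whose analytic Cohen's kappa equals
#' `target_kappa`: cell probabilities `p11 = p^2 + k p q`,
#' `p10 = p01 = p q (1 - k)`, `p00 = q^2 + k p q`. With
#' `method = "quota"` the cell counts are apportioned exactly (so the
#' realized kappa matches the target up to integer rounding of the cells);
#' with `method = "iid"` items are drawn independently and the realized
#' kappa converges to the target as n grows.
#'
#' @param n Number of items.
#' @param target_kappa Target kappa in \[-1, 1\] (the negative range is
#'   limited by `prevalence`; infeasible combinations error).
#' @param prevalence Common positive-label marginal for both annotators.
#' @param seed Integer seed.
#' @param method `"quota"` (exact cell counts) or `"iid"`.
#' @return A list with logical vectors `a` and `b` of length `n`.
#' @export
#' @examples
#' pair <- gen_annotator_pair(40, target_kappa = 0.8, prevalence = 0.5, seed = 7)
#' cohen_kappa(pair$a, pair$b)$kappa
gen_annotator_pair <- function(n, target_kappa, prevalence = 0.5, seed = 1L,
                               method = c("quota", "iid")) {
  method <- match.arg(method)
  stopifnot(n >= 1, prevalence > 0, prevalence < 1,
            target_kappa <= 1)
  p <- prevalence; q <- 1 - p; k <- target_kappa
  cells <- c(tt = p * p + k * p * q, tf = p * q * (1 - k),
             ft = p * q * (1 - k), ff = q * q + k * p * q)
  if (any(cells < -1e-12)) {
    stop("infeasible target_kappa/prevalence combination", call. = FALSE)
  }
  cells <- pmax(cells, 0)
  with_seed(seed, {
    counts <- if (method == "quota") {
      apportion(n, cells)
    } else {
      stats::setNames(as.integer(stats::rmultinom(1, n, cells)), names(cells))
    }
    a <- rep(c(TRUE, TRUE, FALSE, FALSE), counts)
    b <- rep(c(TRUE, FALSE, TRUE, FALSE), counts)
    perm <- sample.int(n)
    list(a = a[perm], b = b[perm])
  })
}
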
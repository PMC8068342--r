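## Independent oracles used by the property tests.  These deliberately do
## not share code with the package internals.

## Brute-force damage classifier: the opposite-strand pair count is taken
## as the size of the MAXIMUM matching among break pairs within dmax bp,
## found by exhaustive enumeration.  For this distance structure the
## package's left-to-right greedy pairing should attain the same count.
oracle_classify <- function(position, strand, is_break, dmax = 10) {
  if (length(position) == 0L) return("EMPTY")
  bp <- position[is_break]
  bs <- strand[is_break]
  nb <- length(bp)
  if (nb == 0L) return("BD")
  if (nb == 1L) return("SSB")
  if (length(unique(bs)) == 1L) return("SSB+")
  pairs <- list()
  for (i in seq_len(nb - 1L)) for (j in (i + 1L):nb)
    if (bs[i] != bs[j] && abs(bp[i] - bp[j]) <= dmax)
      pairs[[length(pairs) + 1L]] <- c(i, j)
  max_matching <- function(avail, used) {
    best <- 0L
    for (k in seq_along(avail)) {
      pr <- avail[[k]]
      if (pr[1] %in% used || pr[2] %in% used) next
      best <- max(best, 1L + max_matching(avail[-seq_len(k)], c(used, pr)))
    }
    best
  }
  d <- if (length(pairs)) max_matching(pairs, integer()) else 0L
  leftover <- nb - 2L * d
  if (d >= 2L) "DSB++"
  else if (d == 1L && leftover >= 1L) "DSB+"
  else if (d == 1L) "DSB"
  else "2SSB"
}

## Exhaustive enumeration of the excision-repair outcome distribution for
## a small cluster: all processing orders (uniform next-lesion choice),
## NER routings and patch lengths, with the translesion-bypass coin
## integrated out analytically.  Returns P(correct, point_mutation,
## repair_dsb).
oracle_repair <- function(position, strand, is_break, params) {
  probs <- c(correct = 0, point_mutation = 0, repair_dsb = 0)
  D <- params$dsb_conversion_distance
  q <- params$q_bypass
  ber_lengths <- switch(params$pathway,
                        SP_BER = , NER_SP_BER = params$sp_patch,
                        params$lp_patch[1]:params$lp_patch[2])
  ner_lengths <- params$ner_patch[1]:params$ner_patch[2]
  use_ner <- params$pathway %in% c("NER_SP_BER", "NER_LP_BER")
  recurse <- function(remaining, bd_alive, open_break, B, w) {
    if (!length(remaining)) {
      pm <- 1 - (1 - q)^B
      probs["point_mutation"] <<- probs["point_mutation"] + w * pm
      probs["correct"] <<- probs["correct"] + w * (1 - pm)
      return(invisible())
    }
    for (i in remaining) {
      wi <- w / length(remaining)
      rest <- setdiff(remaining, i)
      if (is_break[i]) {
        ob <- open_break; ob[i] <- FALSE
        recurse(rest, bd_alive, ob, B, wi)
      } else if (!bd_alive[i]) {
        recurse(rest, bd_alive, open_break, B, wi)
      } else {
        routes <- if (use_ner) c(ber = 1 - params$p_ner, ner = params$p_ner)
                  else c(ber = 1)
        for (r in names(routes)) {
          lens <- if (r == "ner") ner_lengths else ber_lengths
          for (L in lens) {
            wl <- wi * routes[[r]] / length(lens)
            span <- if (strand[i] == 0L) c(position[i], position[i] + L - 1L)
                    else c(position[i] - L + 1L, position[i])
            opp <- strand != strand[i]
            conv <- any(opp & open_break &
                          position >= span[1] - D & position <= span[2] + D)
            if (conv) {
              probs["repair_dsb"] <<- probs["repair_dsb"] + wl
            } else {
              hit <- opp & bd_alive & position >= span[1] & position <= span[2]
              ba <- bd_alive
              ba[!opp & bd_alive & position >= span[1] & position <= span[2]] <- FALSE
              ba[i] <- FALSE
              recurse(rest, ba, open_break, B + sum(hit), wl)
            }
          }
        }
      }
    }
  }
  recurse(seq_along(position), !is_break, is_break, 0L, 1)
  probs
}

## Random small cluster for property tests.
random_cluster <- function(max_lesions = 5, max_pos = 29) {
  n <- sample.int(max_lesions, 1L)
  list(position = sample.int(max_pos + 1L, n, replace = TRUE) - 1L,
       strand = sample(0:1, n, replace = TRUE),
       is_break = sample(c(TRUE, FALSE), n, replace = TRUE))
}
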
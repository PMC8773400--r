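# cardtrace

Evaluating Bluetooth proximity cards as a contact-tracing instrument,
against the traditional alternative: asking people who they met.

During an infectious-disease case investigation, a health official asks a
case to recall their contacts over the preceding days. Bluetooth Low Energy
(BLE) badges — credit-card-sized beacons worn on a lanyard — promise to
automate this, logging every nearby card with a received signal strength
(RSSI) that proxies for distance. Neither instrument observes the truth:
interviews forget, cards are left in drawers. `cardtrace` implements the
statistical toolkit for comparing the two when both were deployed on the
same cohort:

- **a synthetic-data generator** for dyadic contact events, RSSI streams
  under a log-distance path-loss model (`RSSI = RSSI_1m − 20·log10 d + ε`),
  decaying wear compliance, household "cards left at home" artifacts, and
  imperfect interview recall;
- **the card-data pipeline**: 15-second scans → 2-minute windows classified
  by maximum RSSI into proximity classes 0 (≤1 m, RSSI ≥ −50 dBm),
  1 (1–2 m, ≥ −56), 2 (2–4 m, ≥ −62) → 2-hour blocks → daily dyad records,
  plus the symmetric-role and boundary-day cohort filters;
- **directed-network reciprocity**: dyad census (mutual/asymmetric/null),
  traditional reciprocity `r = 2m / (2m + a)` with binomial standard error,
  the Garlaschelli–Loffredo density-adjusted measure
  `ρ̂ = (r − ā)/(1 − ā)` with `ā = ‖A‖ / N(N−1)`, and its
  leave-one-dyad-out jackknife standard error;
- **grouped-binomial logistic models** of daily reciprocity on instrument
  and (polynomial) trial day, with likelihood-ratio tests and a
  basis-invariant instrument odds ratio;
- **concordance analysis**: confusion matrices of card-detected versus
  interview-reported contact events over an explicit dyad-day universe,
  detection rates by proximity-class threshold, daily partial-ROC rates,
  and non-compliance signatures (idle cards; unreported ≥22 h class-0
  dyads).

The package ships the published day-level summary tables of a 7-day,
~1,200-person New Zealand community deployment (the raw logs are not
public), from which every downstream statistic is recomputed exactly.

## Worked example

```r
library(cardtrace)

# Daily reciprocity of the interview-based instrument
tab <- regenerate_reciprocity_table()
tab[tab$dataset == "case_investigation",
    c("date", "r", "sigma_r", "rho_hat", "n_edges")]
#>        date      r sigma_r rho_hat n_edges
#>  2020-11-09 0.7500  0.1083  0.7490      16
#>  2020-11-10 0.4615  0.1383  0.4599      13
#>  2020-11-11 0.6667  0.1361  0.6657      12
#>  2020-11-12 0.6154  0.1349  0.6142      13
#>  2020-11-13 0.7692  0.1169  0.7685      13
#>  2020-11-14 0.5455  0.1501  0.5442      11
#>  2020-11-15 0.6667  0.1361  0.6657      12
```

On any given day only 46–77% of interview-reported contact events were
reported by *both* people involved. The card network is far more
internally consistent:

```r
counts <- reconstruct_reciprocity_counts()
card <- counts[counts$dataset == "card", ]
pooled <- pooled_reciprocity(card$successes, card$trials)
sprintf("Card network: %.2f%% of contact events reciprocated (n = %d)",
        100 * pooled$r, pooled$n)
#> "Card network: 87.72% of contact events reciprocated (n = 6222)"
```

Modelling the daily log-odds of reciprocation on instrument and a
quadratic in trial day:

```r
obs <- reciprocity_model_observations(counts)
m2 <- fit_reciprocity_model(obs, model = 2)
m2
#> <grouped_logit_fit>
#>             Estimate Std. Error      z
#> (Intercept)   0.5525     0.2233 2.4737
#> dataset       1.5578     0.2306 6.7545
#> day_poly1     0.6654     0.1913 3.4794
#> day_poly2     0.8525     0.2473 3.4476
#> Residual deviance 7.860 on 8 df; logLik -30.652

or <- dataset_odds_ratio(m2)
sprintf("Card vs interview odds ratio: %.3f (%.3f, %.3f)",
        or$or, or$ci[1], or$ci[2])
#> "Card vs interview odds ratio: 4.748 (3.022, 7.462)"
```

A card-detected contact event has 4.7 times the odds of being corroborated
by the other party than an interview-reported one. And a fully synthetic
trial, end to end:

```r
cfg <- generator_config(n_participants = 60, n_days = 7, contact_rate = 1,
                        seed = 2026)
trial <- simulate_trial(cfg)
res <- card_pipeline(trial$readings,
                     first_day = cfg$trial_start,
                     last_day = cfg$trial_start + cfg$n_days - 1)
sprintf("%d raw readings -> %d daily dyad records",
        nrow(trial$readings), nrow(res$daily))
#> "978052 raw readings -> 617 daily dyad records"
```

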
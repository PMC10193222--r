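# cbmgames

Headless, seedable game-logic engines for five serious games used in digital
interventions for depression, plus the acceptability analysis that goes with
them.

Cognitive bias modification (CBM) paradigms — retraining negatively biased
attention, interpretation, and imagery — are effective in the laboratory but
repetitive in the field, so they are increasingly delivered as games. This
package re-implements the game logic of five such games as deterministic,
testable state machines, with no rendering, audio, or input handling:

* **Interpretation bias (word search / WSAP).** Each of 42 levels hides an
  ambiguous sentence's words in a letter grid; finding half of them
  (`ceiling(n/2)`) reveals the sentence, then a timed relatedness probe
  trains benign associations. Decoy items (unambiguous sentences with a
  genuinely related negative word) prevent rote yes-to-positive responding.
  The sentence reveal lasts `100 + TC/ARS` ms, with `TC` the character count
  and `ARS` an average reading speed of 50 characters per 1000 ms.
* **Executive control (platformer).** Gameplay (coins, lives, double jumps
  with a doubling life-cost schedule 10, 20, 40, …) is interleaved with
  batches of 3 training rounds: a flanker set (congruent:incongruent 50:50,
  up to 1000 ms), a 100 ms valenced image (neutral 80% after congruent, 20%
  after incongruent), a 50 ms gap, then a colored circle (green:red 50:50,
  up to 2000 ms; green→up, red→down). A round is correct only when both key
  presses are right and in-window.
* **Attention bias (face grids).** Grids with exactly one positive face among
  negative ones; clicking the positive face plays the next note of a song.
  Each 20-song level has time budget `TT = N × T` (`N` notes, `T` per-note
  time adapted within 1000–5000 ms); a staircase tightens `T` and grows the
  grid (1×2 → 2×2 → 3×2) with performance.
* **Positive imagery (interactive fiction).** Two-part ambiguous scenarios
  resolved by free-text completions matched against positive/negative lists;
  after 3 failed attempts the positive list is offered as multiple choice;
  +5 points per positive resolution.
* **Learned helplessness (puzzle suite).** A genuine circle-triangle flip
  puzzle (Lights-Out structure: clicking flips a cell and its orthogonal
  neighbors; solvability and minimal click sets are decided over GF(2)),
  plus three trick mini-games whose later levels are *certified unsolvable*:
  a 15-puzzle broken by a parity-flipping transposition (solvable iff
  inversions + blank row from bottom is odd, for even width), a butterfly
  Hamiltonian-path puzzle (exhaustive search), and an arc-nesting puzzle
  (breadth-first search over the full state space). Giving up on a
  previously solved level ends the game with an explanation of learned
  helplessness and attribution bias.

Simulated agents (skill, interpretation bias, lognormal response times,
persistence, resilience) play every game headlessly and deterministically;
sessions are logged as JSON-Lines event streams. The feedback module maps
5-point Likert labels to scores 2…−2, reports means/SDs, runs exact Wilcoxon
signed-rank tests against 0 (enumeration up to n = 25, continuity-corrected
normal approximation with tie correction beyond), and rounds percentages
half-away-from-zero.

## Worked example

```r
library(cbmgames)

ag <- agent_profile(skill = 0.9, persistence = 5, resilience = 1)
res <- run_session(ag, "helplessness", seed = 42)
res$outcome
#> [1] "ended_explained"
vapply(log_events(res$log, "trick_game_started"),
       function(e) e$payload$game, "")
#> [1] "fifteen"   "butterfly"
```

The agent solves the early circle-triangle levels, gives up when the minimal
solution exceeds its 5-move persistence, is routed through two trick
mini-games (each: one easy level, two certified-unsolvable ones), and —
its resilience exhausted — gives up on a level it had already solved, so the
session ends with the learned-helplessness explanation
(`lh_explanation_text()`).

Feedback analysis on a 15-user Likert table:

```r
print(analyze_feedback(ratings), digits = 3)
#>       game       aspect  n mean    sd statistic        p
#>  attention instructions 15 1.53 0.640       105 0.000122
#>  attention          fun 15 1.13 0.990        75 0.002930
#>  attention      purpose 15 1.20 0.775        78 0.000488
```

Each row is one rated aspect: the mean/SD of the mapped scores and the exact
two-sided Wilcoxon signed-rank p against 0 (e.g. all 15 instruction ratings
positive gives the maximal statistic 105 and p ≈ 1.2e-4).

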
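---
title: "Design of the cbmgames engines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design of the cbmgames engines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbmgames)
```

## What the package models

Cognitive bias modification (CBM) paradigms retrain the negatively biased
attention, interpretation, and mental imagery implicated in depression, and
are increasingly wrapped in games to keep unsupervised users engaged.
`cbmgames` implements the *logic* of five such games — four CBM trainers and
one learned-helplessness demonstration — as deterministic state machines
driven entirely by logical time (integer milliseconds advanced by the
scheduler). Nothing here renders, plays audio, or reads input devices;
everything is observable through event logs, which is what makes the
therapeutic contingencies testable.

Time is logical rather than wall-clock by design: two sessions with the same
seed and the same agent are byte-identical, so every probabilistic claim
about a game can be checked by replaying it.

### Randomness

All stochastic components draw from labelled streams
(`rng_stream(seed, label)`): the substream seed is a hash of the label folded
into the master seed, so adding or removing one game's draws never perturbs
another's. This is plumbing, not science, but it is what allows the
contingency tables below to be audited per subsystem.

## The five engines

### Interpretation bias (word search)

A level hides the words of an ambiguous sentence in a letter grid; word paths
are straight lines of contiguous cells in the eight compass directions (the
classic word-search topology, matching how the deployed game draws them).
Finding 50% of the words reveals the sentence; for odd word counts we use
`ceiling(n/2)`, the stricter reading. The sentence is displayed for
`100 + 20 * TC` ms (`TC` characters; 50 characters per 1000 ms average
reading speed), then a single valenced probe word is judged related or not.

The trained contingency lives in the answer key: for regular items the
correct answer is *yes* exactly for positive probes; decoy items are
unambiguous negative-toned sentences whose negative word genuinely relates,
inverting the mapping so the user cannot succeed by pattern-matching
valence. The shipped 42-item bank is an authored replacement (the deployed
bank is not public) that includes the canonical example sentence; levels are
ordered by `(word count, longest-word length)` ascending, the two difficulty
drivers the design names. The first two levels allot 150 s, the next two
120 s, both with the hidden words shown jumbled; later levels default to
90 s (configurable — the original's per-level schedule beyond level 4 is not
published).

Probe rewards must only be *monotone decreasing in response time* with 0 for
errors; the shape is otherwise free, so we use
`ceiling(max_points * (1 - rt/window))` with a floor of one point, defaults
`max_points = 10`, `window = 5000` ms. Bonus words (valid English words not
in the sentence) score against a small bundled dictionary; words under two
letters never score, which blocks degenerate point farming.

### Executive control (platformer with training rounds)

The platformer is abstracted to its economy and obstacle contract: 3 free
lives, 5 free double jumps, double jumps at 10 coins thereafter, extra lives
at 10, 20, 40, … coins (doubling per purchase), speed +5% per 10 s of
survival capped at 3× base (the ramp constants are engine choices; only
"speed increases" is prescribed). Obstacles demand `run`, `jump`, or
`double_jump`; a wrong action costs a life.

Training batches are exactly three rounds, separated by 2000 ms, each
preceded by an instructions event. Within a round the timeline is fixed:
flanker arrows up to 1000 ms, image for 100 ms, 50 ms blank, circle up to
2000 ms. The stimulus probabilities are the paradigm's active ingredient and
are hard-coded: P(congruent) = 0.5, P(neutral image | congruent) = 0.8,
P(neutral | incongruent) = 0.2, P(green circle) = 0.5, independent
otherwise. By construction the marginal P(negative image) is exactly 0.5 —
the conditioning, not the exposure rate, carries the training. The flanker
set is five arrows (center plus four flankers), the standard configuration.
A round is correct only when both stages are right and in-window; correct
rounds alternate between crediting a double jump and a life (the design says
rewards are one or the other without a rule), and badges fire at 6/15/39
cumulative correct responses. The image is always shown regardless of the
flanker response, preserving the training exposure.

### Attention bias (face grids to music)

Each trial shows exactly one positive face among negatives, the positive
cell uniform over the grid, stimuli sampled without replacement within the
trial. A level is one song of the 20-song bank; the time budget is
`TT = N × T` with `T` initialized to 5000 ms and clamped to [1000, 5000] ms.
Clicking the positive face plays the next note and earns points (default 2);
a negative click beeps and costs one of the 5 per-level lives; at zero lives
the level halts with a replay offer. Points can buy extra time, only offered
at expiry (20 points per 10 s; no rate is published).

The published adaptation algorithm is not available, so the staircase is a
documented engine decision: the ladder orders `(grid, T)` pairs from 1×2 at
5000 ms to 3×2 at 1000 ms; completing a level at accuracy ≥ 0.9 tightens `T`
by 1000 ms, and at the 1000 ms floor the grid grows one step while `T`
resets to 5000 ms; failing, or finishing below 0.6, takes the reverse step.
The thresholds (0.9/0.6) and step (1000 ms) are config defaults. Song note
counts are authored at realistic rhyme lengths (17–62 notes); lives refill
to 5 at each level start (the alternative reading — refill per game — is
ambiguous in the source design). After song 20 the game loops to song 1
preserving the adaptive state. Badges at 34/60/156 positive clicks.

### Positive imagery (interactive fiction)

Scenarios are two-part texts with a blank; the typed phrase is normalized
(lowercase, punctuation stripped, whitespace collapsed — matching is
metamorphic under all three) and matched against per-part positive and
negative completion lists, which must be disjoint after normalization.
Positive resolutions advance (part 1 → part 2 → level conclusion) and earn
5 points; negative resolutions ask the user to try again; unrecognized ones
ask for a different phrase. Both count toward the 3-attempt fallback — the
design says "fails to answer correctly", which both are — after which the
positive list is offered as multiple choice; a selection advances with the
same reward (the source is silent; configurable). No time limit anywhere,
by design (imagery needs unhurried vividness). Badges at 4/10/26 positive
resolutions; after level 19 the game loops to level 0.

### Learned helplessness (puzzle suite)

The genuine puzzle is the circle-triangle flip game: clicking a square flips
it and its orthogonal neighbors ("adjacent" read as von Neumann
neighborhood, the standard convention for this puzzle family). Flips are
involutions and commute, so board states form an affine space over GF(2):
`lights_solve()` performs Gaussian elimination on the click-influence
system and scans the null space (dimension ≤ 4 on the shipped sizes) for a
minimum-weight solution. Levels are generated by applying `k` distinct
random clicks to the solved board — solvable by construction, verified by
the solver anyway. The ladder (levels 1–3 on 3×3 with scramble depth 1–3,
4–6 on 4×4 with depth 3–5, 7+ on 5×5 with growing depth) is an engine
choice; only "multiple difficulty levels" is prescribed, with the top levels
hard enough that finishing the whole game is unlikely.

The three trick mini-games must *look* fair while being provably hopeless:

* **15-puzzle.** Solvability is the standard parity criterion: for odd board
  width, inversions even; for even width, inversions plus the blank's row
  from the bottom (1-based) odd. Unsolvable boards are made by transposing
  two same-row tiles of a well-shuffled solvable scramble — a parity flip —
  then verified, and required to have at most 2 tiles on their solved
  squares so nothing gives the trick away. The easy first level is at most 5
  slides from solved.
* **Butterfly.** Visiting every flower exactly once under orthogonal moves
  onto unwithered flowers is a Hamiltonian-path question, decided exactly by
  memoized depth-first search; "forward and sideways" movement needs no
  extra rule because withering already forbids backtracking.
* **Arc nesting.** The ball/arc movement rules form a small state space
  (ball position, arc placements, containment) explored exhaustively by BFS
  with a witness sequence on success; unsolvable levels are
  rejection-sampled against the verdict.

The session machine alternates circle-triangle play with trick games: give
up → next unused trick game (one easy level, then two unsolvable ones; each
trick game used at most once); give up on both unsolvable levels → replay
the last solved circle-triangle level; give up there → the game ends with
the explanation of learned helplessness and attribution bias (shipped as an
editable text asset, `lh_explanation_text()`); solve it → the ladder
resumes. Completing all circle-triangle levels ends with a gold badge. If
every trick game has been used and the player gives up again, the machine
goes straight to the replay of the last solved level — the published flow is
silent on exhaustion, and this keeps the session finite without inventing a
fourth trick game. Trick order (fifteen → butterfly → arc) is configuration.

## Simulated agents

Agents exist to exercise the logic, not to model humans: they observe full
game state, and their parameters are behavioral dials — `skill`
(per-action success probability), `interpretation_bias` (probability of the
benign probe answer), a lognormal response-time model truncated to each
task's window, `persistence` (move budget before giving up on a puzzle), and
`resilience` (give-up/trick-game cycles tolerated before surrendering on a
previously solved level). `resilience` is what guarantees that every
learned-helplessness session terminates: each pass through the trick games
increments the cycle count, and the agent surrenders once it is exceeded, so
a session ends within `resilience + 1` cycles.

Consequently, passing tests show that the *contingencies and state machines*
behave as designed under any response pattern the profile space can express;
they say nothing about human response-time distributions, fatigue, learning
across sessions, or perceptual errors — none of which the agents model.

## Numerical and convention choices

* Reveal threshold `ceiling(n/2)`; probe reward linear with floor 1;
  percentages rounded half-away-from-zero (so 11/15 → 73, 7/15 → 47, which
  banker's rounding would break).
* Wilcoxon signed-rank against zero: zeros discarded (the classic
  procedure; Pratt's zero-ranking available behind `zero_method = "pratt"`),
  mid-ranks for ties, exact two-sided p for n ≤ 25 via convolution of the
  rank generating functions (identical to enumerating all 2^n sign
  assignments, but linear-time per rank), continuity-corrected normal with
  tie correction above. On tie-free data the two branches agree within 0.02
  at n = 15; on heavily tied 5-point scores the exact law is coarse and gaps
  up to ~0.1 are inherent discreteness, not error.
* SDs are sample SDs (n − 1); a population flag exists because small-sample
  reports cannot always be adjudicated without raw data.
* Grid placement retries are bounded (200 per word, 25 restarts) and raise a
  layout error rather than looping; the arc BFS carries a state-expansion
  cap (10^5, never reached on shipped sizes) returning an explicit
  `undecided` signal.
* Degenerate inputs fail loudly: empty sentences, out-of-range `T`,
  non-increasing badge thresholds, all-zero score vectors, decreasing log
  timestamps.

## Problem sizes

The test suite verifies the solvers against independent oracles at sizes
where exhaustion is exact: all 512 click subsets × all 512 boards for the
3×3 flip puzzle, all 720 tile permutations against BFS reachability for the
2×3 and 3×2 sliding puzzles (360 reachable each), factorial enumeration of
flower orders on 3×3 butterfly boards, and literal sign-assignment
enumeration for the Wilcoxon test. Stochastic checks use 10^4 sampled
training rounds (99% binomial CIs), 10^4 staircase steps, and 10^3 random
learned-helplessness sessions replayed against the state machine.

## Known limitations

* Content banks are authored replacements; the deployed 42-sentence and
  20-scenario banks and the transcribed musical notations are not public.
* The published per-level adaptation schedules for the word-search and
  attention games are unavailable; the ladders above are documented
  stand-ins with the stated drivers.
* The platformer is an economy-and-contract abstraction; no physics.
* Completion matching is list membership after normalization — by design
  (that is the deployed mechanism), so free text outside the lists is
  "unrecognized" rather than inferred.
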
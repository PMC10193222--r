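Some of the puzzles you just played could not be solved, no matter what you
tried. The last puzzle, however, was one you had already solved earlier.

If you gave up on it, you experienced a small dose of learned helplessness:
after repeated failures on impossible tasks, we start to assume that failure
is about us, and we stop trying even where we have already succeeded.

This habit of explaining failures as personal ("I am not able"), pervasive
("I fail at everything") and persistent ("it will always be like this") is
called a dysfunctional attribution style. The failures you just experienced
were caused by the puzzles, not by you - the game made them impossible.

In real life it is worth checking, each time something goes wrong, whether
the cause really is personal and pervasive, or whether the situation itself
was rigged against you. Evaluating each situation on its own keeps a failure
in one area from draining your motivation in all the others.
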
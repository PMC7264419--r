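"""Independent symbolic oracle for two-event situation solving.

Reads a JSON list of cases from the path given as argv[1]; each case is a
list of constraints over the four cell probabilities
x = (P(A&B), P(A&notB), P(notA&B), P(notA&notB)):

  {"type": "marginal",    "event": "A",  "num": 1, "den": 50}
  {"type": "joint",       "cell": 0,     "num": 2, "den": 125}
  {"type": "conditional", "target": "B", "given": "A", "num": 4, "den": 5}

Builds the exact linear system (plus normalization sum(x) = 1) with sympy
Rationals and decides the status by rank inspection and brute-force
enumeration of basic solutions of the bounded polytope {Ax = b, 0 <= x <= 1}:

  complete        unique solution inside the bounds
  underdetermined solution space of dimension >= 1 that meets the simplex
  inconsistent    otherwise

Writes a JSON list of status strings to the path given as argv[2].
"""
import itertools
import json
import sys

import sympy as sp

EVENTS = {
    "A":    (1, 1, 0, 0),
    "notA": (0, 0, 1, 1),
    "B":    (1, 0, 1, 0),
    "notB": (0, 1, 0, 1),
}


def rows_for(constraints):
    rows = [[sp.Integer(1)] * 4 + [sp.Integer(1)]]  # normalization
    for c in constraints:
        v = sp.Rational(c["num"], c["den"])
        if c["type"] == "marginal":
            coef = [sp.Integer(k) for k in EVENTS[c["event"]]]
            rows.append(coef + [v])
        elif c["type"] == "joint":
            coef = [sp.Integer(0)] * 4
            coef[c["cell"]] = sp.Integer(1)
            rows.append(coef + [v])
        elif c["type"] == "conditional":
            tgt = EVENTS[c["target"]]
            giv = EVENTS[c["given"]]
            joint = [t * g for t, g in zip(tgt, giv)]
            coef = [sp.Integer(j) - v * sp.Integer(g)
                    for j, g in zip(joint, giv)]
            rows.append(coef + [sp.Integer(0)])
        else:
            raise ValueError(c["type"])
    return rows


def in_bounds(x):
    return all(0 <= xi <= 1 for xi in x)


def satisfies(rows, x):
    for row in rows:
        if sum(c * xi for c, xi in zip(row[:4], x)) != row[4]:
            return False
    return True


def feasible_vertex(rows, dof):
    for k in range(dof, 4):
        for subset in itertools.combinations(range(4), k):
            free = [i for i in range(4) if i not in subset]
            for bounds in itertools.product((0, 1), repeat=k):
                sub_a, sub_b = [], []
                for row in rows:
                    rhs = row[4] - sum(row[subset[i]] * bounds[i]
                                       for i in range(k))
                    sub_a.append([row[j] for j in free])
                    sub_b.append(rhs)
                m = sp.Matrix(sub_a)
                b = sp.Matrix(sub_b)
                if m.rank() != len(free):
                    continue
                if sp.Matrix.hstack(m, b).rank() != m.rank():
                    continue
                sol = list(sp.linsolve((m, b)))
                if not sol:
                    continue
                xs = list(sol[0])
                x = [sp.Integer(0)] * 4
                for i, s in enumerate(subset):
                    x[s] = sp.Integer(bounds[i])
                for i, f in enumerate(free):
                    x[f] = xs[i]
                if in_bounds(x) and satisfies(rows, x):
                    return True
    return False


def zero_marginal_conflict(constraints, x):
    """A conditional conditioning on an event forced to probability 0."""
    for c in constraints:
        if c["type"] != "conditional":
            continue
        giv = EVENTS[c["given"]]
        marg = sum(sp.Integer(g) * xi for g, xi in zip(giv, x))
        if marg == 0:
            return True
    return False


def status_of(constraints):
    rows = rows_for(constraints)
    a_mat = sp.Matrix([r[:4] for r in rows])
    aug = sp.Matrix([r for r in rows])
    r_a = a_mat.rank()
    if aug.rank() > r_a:
        return "inconsistent"
    dof = 4 - r_a
    if dof == 0:
        sol = list(sp.linsolve((a_mat, sp.Matrix([r[4] for r in rows]))))
        x = list(sol[0])
        if not in_bounds(x):
            return "inconsistent"
        if zero_marginal_conflict(constraints, x):
            return "inconsistent"
        return "complete"
    if not feasible_vertex(rows, dof):
        return "inconsistent"
    return "underdetermined"


def main():
    with open(sys.argv[1]) as fh:
        cases = json.load(fh)
    out = [status_of(case) for case in cases]
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
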
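#include <Rcpp.h>
using namespace Rcpp;

// Glocal profile-to-sequence alignment: the profile is consumed in full,
// the sequence contributes a local window. Affine gaps in both directions;
// a gap of length g costs gapOpen + g * gapExtend. Masked sequence
// positions cannot be matched or inserted, so no hit can span them.
//
// prof: nrow = alphabet size, ncol = L profile columns.
// seqIdx: 0-based alphabet row index per sequence position.
// Returns best score with 1-based start/end of the sequence window
// (score = -Inf when no unmasked window exists).
// [[Rcpp::export(name = ".profile_align_core")]]
List profile_align_core(NumericMatrix prof, IntegerVector seqIdx,
                        LogicalVector mask, double gapOpen, double gapExtend) {
    const int L = prof.ncol();
    const int n = seqIdx.size();
    const double NEG = -1e18;
    const double openCost = gapOpen + gapExtend;

    // DP rows over profile columns; columns over sequence prefix length.
    // M: col i matched to residue j; Ix: residue j inserted (gap in
    // profile); Iy: col i deleted (gap in sequence).
    std::vector<double> Mprev(n + 1, NEG), Mcur(n + 1, NEG);
    std::vector<double> Ixprev(n + 1, NEG), Ixcur(n + 1, NEG);
    std::vector<double> Iyprev(n + 1, NEG), Iycur(n + 1, NEG);
    std::vector<int> sMprev(n + 1, 0), sMcur(n + 1, 0);
    std::vector<int> sIxprev(n + 1, 0), sIxcur(n + 1, 0);
    std::vector<int> sIyprev(n + 1, 0), sIycur(n + 1, 0);

    // Row 0: zero profile columns consumed. Free sequence prefix: an
    // alignment starting after position j has base score 0, start j+1.
    for (int j = 0; j <= n; ++j) { Mprev[j] = 0.0; sMprev[j] = j + 1; }
    // Deleting leading profile columns is a normal internal gap.
    Iyprev[0] = NEG;  // filled per-row below

    std::vector<double> IyprevRow = Iyprev;  // Iy for row 0 is -inf
    std::vector<double>& Iy0 = IyprevRow;
    (void)Iy0;

    for (int i = 1; i <= L; ++i) {
        Mcur[0] = NEG;
        Ixcur[0] = NEG;
        // Column j = 0: only deletions of profile columns possible.
        double del0 = (i == 1) ? (Mprev[0] - openCost) : (Iyprev[0] - gapExtend);
        double delM = Mprev[0] - openCost;
        Iycur[0] = (i == 1) ? del0 : std::max(delM, del0);
        sIycur[0] = 1;
        for (int j = 1; j <= n; ++j) {
            const bool masked = mask[j - 1];
            // Match state
            double diagM = Mprev[j - 1], diagIx = Ixprev[j - 1], diagIy = Iyprev[j - 1];
            double best = diagM; int sbest = sMprev[j - 1];
            if (diagIx > best) { best = diagIx; sbest = sIxprev[j - 1]; }
            if (diagIy > best) { best = diagIy; sbest = sIyprev[j - 1]; }
            if (masked || best <= NEG / 2) {
                Mcur[j] = NEG; sMcur[j] = 0;
            } else {
                Mcur[j] = best + prof(seqIdx[j - 1], i - 1);
                sMcur[j] = sbest;
            }
            // Insertion (consume sequence residue, gap in profile)
            if (masked) {
                Ixcur[j] = NEG; sIxcur[j] = 0;
            } else {
                double a = Mcur[j - 1] - openCost;
                double b = Ixcur[j - 1] - gapExtend;
                double c = Iycur[j - 1] - openCost;
                double ibest = a; int sib = sMcur[j - 1];
                if (b > ibest) { ibest = b; sib = sIxcur[j - 1]; }
                if (c > ibest) { ibest = c; sib = sIycur[j - 1]; }
                Ixcur[j] = (ibest <= NEG / 2) ? NEG : ibest;
                sIxcur[j] = sib;
            }
            // Deletion (consume profile column, gap in sequence)
            {
                double a = Mprev[j] - openCost;
                double b = Iyprev[j] - gapExtend;
                double c = Ixprev[j] - openCost;
                double dbest = a; int sdb = sMprev[j];
                if (b > dbest) { dbest = b; sdb = sIyprev[j]; }
                if (c > dbest) { dbest = c; sdb = sIxprev[j]; }
                Iycur[j] = (dbest <= NEG / 2) ? NEG : dbest;
                sIycur[j] = sdb;
            }
        }
        std::swap(Mprev, Mcur); std::swap(Ixprev, Ixcur); std::swap(Iyprev, Iycur);
        std::swap(sMprev, sMcur); std::swap(sIxprev, sIxcur); std::swap(sIyprev, sIycur);
    }

    // Alignment ends once the profile is consumed (ignore trailing
    // insertions, they can only lower the score).
    double best = NEG; int bestEnd = 0, bestStart = 0;
    for (int j = 1; j <= n; ++j) {
        if (Mprev[j] > best) { best = Mprev[j]; bestEnd = j; bestStart = sMprev[j]; }
        if (Iyprev[j] > best) { best = Iyprev[j]; bestEnd = j; bestStart = sIyprev[j]; }
    }
    // All-deletion alignment (empty window) is never a useful hit.
    if (best <= NEG / 2 || bestEnd < bestStart) {
        return List::create(_["score"] = R_NegInf, _["start"] = NA_INTEGER,
                            _["end"] = NA_INTEGER);
    }
    return List::create(_["score"] = best, _["start"] = bestStart,
                        _["end"] = bestEnd);
}
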
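"""Epoch a BCI Competition IV GDF file and write a tcformer trial store.

Usage: read_gdf.py <in.gdf> <out.tcfstore> <window_start_s> <window_s> <fs> <name>

EEG channels only (EOG dropped); cue events mapped to 0-based class labels.
"""
import json
import struct
import sys

import numpy as np
import mne


def write_store(path, signals, labels, fs, ch_names, subject, session, n_classes):
    n_trials, n_ch, n_samp = signals.shape
    entry = {
        "dims": [int(n_trials), int(n_ch), int(n_samp)],
        "labels": [int(v) for v in labels],
        "fs": float(fs),
        "channel_names": list(ch_names),
        "subject": subject,
        "session": session,
        "n_classes": int(n_classes),
        "trial_ids": ["%s:%s:%04d" % (subject, session, i + 1) for i in range(n_trials)],
        "metadata": {},
        "offset": 0,
        "n_values": int(signals.size),
    }
    hdr = json.dumps({"format": "tcformer-trial-store", "version": 1,
                      "entries": [entry]}).encode()
    # R stores [trial, channel, time] column-major = trial index fastest
    payload = np.ascontiguousarray(np.transpose(signals, (2, 1, 0))).astype("<f8")
    with open(path, "wb") as fh:
        fh.write(b"TCFSTOR1")
        fh.write(struct.pack("<d", float(len(hdr))))
        fh.write(hdr)
        fh.write(payload.tobytes())


def main():
    gdf, out, t0, dur, fs_target, name = sys.argv[1:7]
    t0, dur, fs_target = float(t0), float(dur), float(fs_target)
    raw = mne.io.read_raw_gdf(gdf, preload=True, verbose="error")
    eog = [ch for ch in raw.ch_names if "EOG" in ch.upper()]
    if eog:
        raw.drop_channels(eog)
    if abs(raw.info["sfreq"] - fs_target) > 1e-6:
        raw.resample(fs_target)
    events, event_id = mne.events_from_annotations(raw, verbose="error")
    # cue codes: IV-2a 769..772 -> classes 0..3; IV-2b 769/770 -> 0/1
    cue_names = [k for k in event_id if k in ("769", "770", "771", "772")]
    if not cue_names:
        known = ", ".join(sorted(event_id))
        raise SystemExit("no cue event codes (769-772) found; events present: " + known)
    cue_names.sort()
    keep = {event_id[k]: i for i, k in enumerate(cue_names)}
    picks = events[np.isin(events[:, 2], list(keep)), :]
    epochs = mne.Epochs(raw, picks, tmin=t0, tmax=t0 + dur,
                        baseline=None, preload=True, verbose="error")
    x = epochs.get_data()[:, :, : int(round(dur * fs_target))] * 1e6  # volts -> uV
    y = np.array([keep[c] for c in epochs.events[:, 2]])
    write_store(out, x, y, fs_target, epochs.ch_names, name, "train", len(cue_names))


if __name__ == "__main__":
    main()
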
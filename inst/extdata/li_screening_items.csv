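item,text
1,Patient reports his/her back has collapsed.
2,Patient frequently self-manipulates to decrease their symptoms.
3,Patient's back pain symptoms alternate periodically.
4,Patient has a history of complaints of stiffness and sudden back pain when twisting or bending their back.
5,"Patient's back pain has been provoked by changing posture, for example standing up from sitting, etc."
6,Patient has increased back pain when returning to upright after forward bending.
7,Sudden or minor movements increase patient's back pain.
8,Patient gets worse when sitting on a chair without a backrest and gets better when sitting on a chair with backrest.
9,Patient reports being in a static posture for a long time has an effect on their back problem.
10,Patient's back pain is worsening.
11,Patient wears a brace or corset to temporarily alleviate back pain.
12,Patient with back problems regularly experiences muscle spasms.
13,Patient avoids or hesitates to move when they have back symptoms.
14,Patient has a past history of back injury.
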
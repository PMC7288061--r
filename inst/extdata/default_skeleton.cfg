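# skeleton definition
lengths = trunk,head,clav,pelv,ua_r,ua_l,fa_r,fa_l,th_r,th_l,sh_r,sh_l
anthropometry = 0.5 0.25 0.17 0.14 0.3 0.3 0.26 0.26 0.42 0.42 0.41 0.41
[joint 1]
name = base_yaw
parent = 0
axis = 0 1 0
limits_deg = -180 180
group = base
qgroup = base_rot
[joint 2]
name = base_pitch
parent = 1
axis = 1 0 0
limits_deg = -60 60
group = base
qgroup = base_rot
[joint 3]
name = base_roll
parent = 2
axis = 0 0 1
limits_deg = -60 60
group = base
qgroup = base_rot
[joint 4]
name = r_hip_flex
parent = 3
axis = -1 -0 -0
limits_deg = -30 130
group = leg
qgroup = leg_hip_flex
trans.pelv = -0.7071067812 -0.7071067812 0
[joint 5]
name = r_hip_abd
parent = 4
axis = -0 -0 -1
limits_deg = -30 50
group = leg
qgroup = leg_hip_abd
[joint 6]
name = r_hip_rot
parent = 5
axis = 0 1 0
limits_deg = -45 45
group = leg
qgroup = leg_hip_rot
[joint 7]
name = r_knee
parent = 6
axis = 1 0 0
limits_deg = -5 150
group = leg
qgroup = leg_knee
trans.th_r = -0 -1 -0
[joint 8]
name = l_hip_flex
parent = 3
axis = -1 -0 -0
limits_deg = -30 130
group = leg
qgroup = leg_hip_flex
trans.pelv = 0.7071067812 -0.7071067812 0
[joint 9]
name = l_hip_abd
parent = 8
axis = 0 0 1
limits_deg = -30 50
group = leg
qgroup = leg_hip_abd
[joint 10]
name = l_hip_rot
parent = 9
axis = 0 1 0
limits_deg = -45 45
group = leg
qgroup = leg_hip_rot
[joint 11]
name = l_knee
parent = 10
axis = 1 0 0
limits_deg = -5 150
group = leg
qgroup = leg_knee
trans.th_l = -0 -1 -0
[joint 12]
name = trunk_flex
parent = 3
axis = 1 0 0
limits_deg = -30 90
group = trunk
qgroup = trunk
[joint 13]
name = r_clav
parent = 12
axis = -0 -0 -1
limits_deg = -10 45
group = trunk
qgroup = trunk
trans.trunk = 0 1 0
[joint 14]
name = r_sh_abd
parent = 13
axis = -0 -0 -1
limits_deg = -30 180
group = arm
qgroup = arm_sh_abd
trans.clav = -1 -0 -0
[joint 15]
name = r_sh_flex
parent = 14
axis = -1 -0 -0
limits_deg = -60 180
group = arm
qgroup = arm_sh_flex
[joint 16]
name = r_sh_rot
parent = 15
axis = 0 1 0
limits_deg = -90 90
group = arm
qgroup = arm_sh_rot
[joint 17]
name = r_elbow
parent = 16
axis = -1 -0 -0
limits_deg = -5 150
group = arm
qgroup = arm_elbow
trans.ua_r = -0 -1 -0
[joint 18]
name = l_clav
parent = 12
axis = 0 0 1
limits_deg = -10 45
group = trunk
qgroup = trunk
trans.trunk = 0 1 0
[joint 19]
name = l_sh_abd
parent = 18
axis = 0 0 1
limits_deg = -30 180
group = arm
qgroup = arm_sh_abd
trans.clav = 1 0 0
[joint 20]
name = l_sh_flex
parent = 19
axis = -1 -0 -0
limits_deg = -60 180
group = arm
qgroup = arm_sh_flex
[joint 21]
name = l_sh_rot
parent = 20
axis = 0 1 0
limits_deg = -90 90
group = arm
qgroup = arm_sh_rot
[joint 22]
name = l_elbow
parent = 21
axis = -1 -0 -0
limits_deg = -5 150
group = arm
qgroup = arm_elbow
trans.ua_l = -0 -1 -0
[jcp 1]
name = spine_base
frame = 3
[jcp 2]
name = spine_shoulder
frame = 12
offset.trunk = 0 1 0
[jcp 3]
name = head
frame = 12
offset.trunk = 0 1 0
offset.head = 0 1 0
[jcp 4]
name = r_shoulder
frame = 14
[jcp 5]
name = r_elbow
frame = 17
[jcp 6]
name = r_wrist
frame = 17
offset.fa_r = 0 -1 0
[jcp 7]
name = l_shoulder
frame = 19
[jcp 8]
name = l_elbow
frame = 22
[jcp 9]
name = l_wrist
frame = 22
offset.fa_l = 0 -1 0
[jcp 10]
name = r_hip
frame = 4
[jcp 11]
name = r_knee
frame = 7
[jcp 12]
name = r_ankle
frame = 7
offset.sh_r = 0 -1 0
[jcp 13]
name = l_hip
frame = 8
[jcp 14]
name = l_knee
frame = 11
[jcp 15]
name = l_ankle
frame = 11
offset.sh_l = 0 -1 0
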